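# Five classifier families behind one grid-search interface.
#
# Backends: in-package Gaussian naive Bayes (variance smoothing), rpart
# (decision tree), ranger (random forest), glmnet (multinomial logistic
# regression), xgboost (gradient boosting), plus an optional e1071 SVM.
# Hyperparameter names follow the conventional sklearn-style grid
# vocabulary; each backend maps them to its own arguments (see vignette).

.algorithms <- c("nb", "dt", "rf", "lr", "xgb", "svm")

#' Default hyperparameter grid per algorithm
#'
#' The shipped grids follow the published search space for each family,
#' with backend-imposed adjustments: tree depth candidates above rpart's
#' hard cap of 30 collapse to 30, "None" depth maps to unlimited (0), and
#' the gradient-boosting `max_features` candidate set is mapped to per-tree
#' column subsampling.  Grids are plain named lists, so callers can pass a
#' reduced grid for desk-scale runs.
#'
#' @param algorithm One of `"nb"`, `"dt"`, `"rf"`, `"lr"`, `"xgb"`,
#'   `"svm"`.
#' @return Named list of candidate value vectors.
#' @export
#' @examples
#' default_grid("dt")
default_grid <- function(algorithm) {
  switch(match.arg(algorithm, .algorithms),
    nb = list(var_smoothing = 10^seq(-9, -3)),
    lr = list(penalty = c("l1", "l2"),
              C = c(0.001, 0.01, 0.1, 1, 10, 100, 1000)),
    dt = list(criterion = c("gini", "information"),
              max_depth = c(10, 20, 30),
              min_samples_leaf = c(1, 2, 4),
              min_samples_split = c(2, 5, 10)),
    rf = list(bootstrap = c(TRUE, FALSE),
              max_depth = c(10, 20, 30, 40, 50, 0),
              max_features = c("auto", "sqrt"),
              min_samples_leaf = c(1, 2, 4),
              min_samples_split = c(2, 5, 10),
              n_estimators = c(20, 40, 60, 80, 100, 200, 500, 1000, 1500)),
    xgb = list(max_depth = c(10, 20, 30, 40, 50, 0),
               max_features = c("auto", "sqrt"),
               min_samples_leaf = c(1, 2, 4),
               n_estimators = c(20, 40, 60, 80, 100, 200, 500, 1000, 1500)),
    svm = list(C = c(0.001, 0.01, 0.1, 1, 10, 100, 1000),
               gamma = seq(0.1, 1.0, by = 0.1),
               kernel = c("radial", "linear"))
  )
}

#' Model specification
#'
#' Bundles the algorithm, its hyperparameter grid, the number of CV folds
#' and the grid-selection metric.
#'
#' @param algorithm One of `"nb"`, `"dt"`, `"rf"`, `"lr"`, `"xgb"`,
#'   `"svm"`.
#' @param grid Named list of candidate values (default [default_grid()]).
#' @param cv_folds Number of stratified CV folds (default 5).
#' @param scoring `"macro_f1"` (default) or `"accuracy"`.
#' @return A `ddi_model_spec` object.
#' @export
#' @examples
#' model_spec("xgb", grid = list(max_depth = c(6, 10), n_estimators = 100))
model_spec <- function(algorithm, grid = default_grid(algorithm),
                       cv_folds = 5, scoring = c("macro_f1", "accuracy")) {
  algorithm <- match.arg(algorithm, .algorithms)
  scoring <- match.arg(scoring)
  stopifnot(cv_folds >= 2, is.list(grid), !is.null(names(grid)))
  structure(list(algorithm = algorithm, grid = grid,
                 cv_folds = as.integer(cv_folds), scoring = scoring),
            class = "ddi_model_spec")
}

#' @export
print.ddi_model_spec <- function(x, ...) {
  cat("<ddi_model_spec ", x$algorithm, ": ",
      prod(lengths(x$grid)), " grid point(s), ", x$cv_folds,
      "-fold CV, scoring ", x$scoring, ">\n", sep = "")
  invisible(x)
}

# stratified fold assignment, deterministic given seed
.stratified_folds <- function(y, k, seed) {
  counts <- table(y)
  if (any(counts < k)) {
    small <- names(counts)[counts < k]
    abort(paste0("class(es) ", paste(small, collapse = ", "), " have fewer ",
                 "members than cv_folds = ", k, "; lower cv_folds or apply ",
                 "a stronger filter_low_count_classes() cutoff"),
          class = "ddihybrid_error")
  }
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (lev in names(counts)) {
      ix <- sample(which(y == lev))
      folds[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  folds
}

.class_levels <- function(y) {
  u <- unique(y)
  if (is.numeric(u)) as.character(sort(u)) else sort(as.character(u))
}

#' Cross-validated grid search
#'
#' Evaluates every grid point with stratified k-fold cross-validation,
#' picks the best by mean score (ties resolved by grid order), and refits
#' on the full training input.  When a `balance` function is supplied
#' (e.g. a [smote_balance()] wrapper), it is applied inside each training
#' fold only, never to validation folds, and again to the full data for the
#' final refit.
#'
#' @param x Data frame or matrix of named numeric features.
#' @param y Class labels.
#' @param spec A [model_spec()].
#' @param seed Integer seed controlling folds and stochastic learners.
#' @param balance Optional `function(x, y)` returning `list(x = , y = )`.
#' @return A `ddi_model`: spec, `best_params`, per-fold scores of the best
#'   grid point, full `cv_results`, the fitted predictor, feature names and
#'   the class catalog.
#' @export
grid_search_cv <- function(x, y, spec, seed = 1L, balance = NULL) {
  stopifnot(inherits(spec, "ddi_model_spec"))
  m <- if (is.matrix(x)) x else .as_feature_matrix(x)
  feature_names <- colnames(m)
  label_type <- if (is.numeric(y)) "integer" else "character"
  lev <- .class_levels(y)
  yf <- factor(as.character(y), levels = lev)
  scorer <- if (spec$scoring == "macro_f1") .macro_f1 else .accuracy

  if (length(lev) < 2) {
    # degenerate single-class input: constant predictor, no search
    fit <- list(kind = "constant", class = lev)
    return(.new_ddi_model(spec, list(), rep(NA_real_, spec$cv_folds),
                          tibble(), fit, feature_names, lev, label_type,
                          integer(length(y)), seed))
  }

  grid_tbl <- expand.grid(spec$grid, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
  folds <- .stratified_folds(yf, spec$cv_folds, seed)
  score_mat <- matrix(NA_real_, nrow(grid_tbl), spec$cv_folds)
  for (g in seq_len(nrow(grid_tbl))) {
    params <- as.list(grid_tbl[g, , drop = FALSE])
    for (f in seq_len(spec$cv_folds)) {
      tr <- folds != f
      xtr <- m[tr, , drop = FALSE]; ytr <- yf[tr]
      if (!is.null(balance)) {
        b <- balance(xtr, ytr)
        xtr <- if (is.matrix(b$x)) b$x else .as_feature_matrix(b$x)
        ytr <- factor(as.character(b$y), levels = lev)
      }
      fit <- .fit_algorithm(spec$algorithm, xtr, ytr, params,
                            seed = seed + f)
      pred <- .predict_algorithm(fit, m[!tr, , drop = FALSE],
                                 type = "class")
      score_mat[g, f] <- scorer(as.character(yf[!tr]), pred)
    }
  }
  mean_scores <- rowMeans(score_mat)
  best <- which.max(mean_scores)  # ties: first grid point
  best_params <- as.list(grid_tbl[best, , drop = FALSE])

  xfull <- m; yfull <- yf
  if (!is.null(balance)) {
    b <- balance(xfull, yfull)
    xfull <- if (is.matrix(b$x)) b$x else .as_feature_matrix(b$x)
    yfull <- factor(as.character(b$y), levels = lev)
  }
  fit <- .fit_algorithm(spec$algorithm, xfull, yfull, best_params,
                        seed = seed)
  cv_results <- bind_cols(
    as_tibble(grid_tbl),
    tibble(mean_score = mean_scores,
           sd_score = apply(score_mat, 1, sd))
  )
  .new_ddi_model(spec, best_params, score_mat[best, ], cv_results, fit,
                 feature_names, lev, label_type, folds, seed)
}

.new_ddi_model <- function(spec, best_params, fold_scores, cv_results, fit,
                           feature_names, classes, label_type, folds, seed) {
  structure(
    list(spec = spec, best_params = best_params, fold_scores = fold_scores,
         cv_results = cv_results, fit = fit, feature_names = feature_names,
         classes = classes, label_type = label_type, folds = folds,
         seed = seed),
    class = "ddi_model"
  )
}

#' @export
print.ddi_model <- function(x, ...) {
  cat("<ddi_model ", x$spec$algorithm, ">\n", sep = "")
  if (length(x$best_params)) {
    cat("best params:",
        paste(names(x$best_params), unlist(x$best_params), sep = "=",
              collapse = ", "), "\n")
    cat("mean CV", x$spec$scoring, "=",
        round(mean(x$fold_scores), 4), "\n")
  }
  cat(length(x$classes), "classes,", length(x$feature_names), "features\n")
  invisible(x)
}

#' Tidy and glance methods for fitted models
#'
#' `tidy()` returns the full cross-validation results (one row per grid
#' point); `glance()` a one-row model summary.
#'
#' @param x A `ddi_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ddi_model <- function(x, ...) x$cv_results

#' @rdname tidy.ddi_model
#' @export
glance.ddi_model <- function(x, ...) {
  tibble(
    algorithm = x$spec$algorithm,
    best_params = paste(names(x$best_params), unlist(x$best_params),
                        sep = "=", collapse = ", "),
    mean_cv_score = mean(x$fold_scores),
    sd_cv_score = sd(x$fold_scores),
    cv_folds = x$spec$cv_folds,
    scoring = x$spec$scoring,
    n_classes = length(x$classes),
    n_features = length(x$feature_names)
  )
}

# align prediction input to the training schema, by name
.align_features <- function(model, newdata) {
  m <- if (is.matrix(newdata)) newdata else .as_feature_matrix(newdata)
  missing <- setdiff(model$feature_names, colnames(m))
  extra <- setdiff(colnames(m), model$feature_names)
  if (length(missing) || length(extra)) {
    abort(paste0(
      "feature schema mismatch",
      if (length(missing)) paste0("; missing: ",
                                  paste(head(missing, 5), collapse = ", ")),
      if (length(extra)) paste0("; unexpected: ",
                                paste(head(extra, 5), collapse = ", "))
    ), class = "ddihybrid_schema_error")
  }
  m[, model$feature_names, drop = FALSE]
}

#' Predict interaction classes or class scores
#'
#' @param object A `ddi_model`.
#' @param newdata Data frame or matrix with the training feature schema
#'   (any column order; matched by name).
#' @param type `"class"` for labels, `"prob"` for the per-class score
#'   matrix (rows sum to 1, columns in catalog order).
#' @param ... Unused.
#' @return Labels (same type as the training labels) or a numeric matrix.
#' @export
predict.ddi_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  m <- .align_features(object, newdata)
  if (nrow(m) == 0) {
    if (type == "class") {
      return(if (object$label_type == "integer") integer() else character())
    }
    return(matrix(numeric(), 0, length(object$classes),
                  dimnames = list(NULL, object$classes)))
  }
  out <- .predict_algorithm(object$fit, m, type = type,
                            classes = object$classes)
  if (type == "class" && object$label_type == "integer") {
    out <- as.integer(out)
  }
  out
}

#' @rdname predict.ddi_model
#' @param model A `ddi_model`.
#' @export
predict_scores <- function(model, newdata) {
  predict(model, newdata, type = "prob")
}

# ---- per-algorithm fitting --------------------------------------------------

.fit_algorithm <- function(algorithm, x, y, params, seed) {
  y <- droplevels(y)
  if (nlevels(y) < 2) {
    return(list(kind = "constant", class = levels(y)))
  }
  withr::with_seed(seed, switch(algorithm,
    nb = .fit_gnb(x, y, params),
    dt = .fit_dt(x, y, params),
    rf = .fit_rf(x, y, params, seed),
    lr = .fit_lr(x, y, params),
    xgb = .fit_xgb(x, y, params),
    svm = .fit_svm(x, y, params)
  ))
}

# Gaussian naive Bayes with sklearn-style variance smoothing: each class
# variance gets  var_smoothing * max feature variance  added.
.fit_gnb <- function(x, y, params) {
  eps <- (params$var_smoothing %||% 1e-9) * max(apply(x, 2, var), 1e-12)
  levs <- levels(y)
  mu <- lapply(levs, function(l) colMeans(x[y == l, , drop = FALSE]))
  s2 <- lapply(levs, function(l) {
    v <- apply(x[y == l, , drop = FALSE], 2, var)
    v[is.na(v)] <- 0
    v + eps
  })
  list(kind = "gnb", levels = levs, prior = as.numeric(table(y)) / length(y),
       mu = mu, s2 = s2)
}

.fit_dt <- function(x, y, params) {
  df <- as.data.frame(x)
  safe <- paste0("F", seq_len(ncol(x)))
  colnames(df) <- safe
  df$.outcome <- y
  fit <- rpart::rpart(
    .outcome ~ ., data = df, method = "class",
    parms = list(split = params$criterion %||% "gini"),
    control = rpart::rpart.control(
      maxdepth = min(params$max_depth %||% 30, 30),
      minsplit = params$min_samples_split %||% 2,
      minbucket = params$min_samples_leaf %||% 1,
      cp = 1e-4, xval = 0
    )
  )
  list(kind = "dt", fit = fit, safe_names = safe)
}

.fit_rf <- function(x, y, params, seed) {
  p <- ncol(x)
  fit <- ranger::ranger(
    x = x, y = y, probability = TRUE,
    num.trees = params$n_estimators %||% 500,
    max.depth = params$max_depth %||% 0,
    mtry = max(1, floor(sqrt(p))),  # both "auto" and "sqrt" candidates
    min.node.size = params$min_samples_split %||% 2,
    min.bucket = params$min_samples_leaf %||% 1,
    replace = params$bootstrap %||% TRUE,
    sample.fraction = 1,  # bootstrap = FALSE grows each tree on all rows
    seed = seed, num.threads = 1, verbose = FALSE
  )
  list(kind = "rf", fit = fit)
}

.fit_lr <- function(x, y, params) {
  alpha <- if (identical(params$penalty %||% "l2", "l1")) 1 else 0
  lambda <- 1 / ((params$C %||% 1) * nrow(x))
  fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = alpha,
                        lambda = lambda)
  list(kind = "lr", fit = fit, lambda = lambda)
}

.fit_xgb <- function(x, y, params) {
  levs <- levels(y)
  depth <- params$max_depth %||% 6
  colsample <- if (identical(params$max_features %||% "auto", "sqrt")) {
    max(sqrt(ncol(x)) / ncol(x), 1 / ncol(x))
  } else 1
  xgb_params <- list(
    objective = "multi:softprob", num_class = length(levs),
    max_depth = depth, min_child_weight = params$min_samples_leaf %||% 1,
    colsample_bytree = colsample, eta = 0.3,
    tree_method = "hist", nthread = 1
  )
  if (depth == 0) xgb_params$grow_policy <- "lossguide"
  dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
  fit <- xgboost::xgb.train(params = xgb_params, data = dtrain,
                            nrounds = params$n_estimators %||% 100,
                            verbose = 0)
  list(kind = "xgb", fit = fit, levels = levs)
}

.fit_svm <- function(x, y, params) {
  fit <- e1071::svm(
    x = x, y = y, probability = TRUE,
    cost = params$C %||% 1, gamma = params$gamma %||% (1 / ncol(x)),
    kernel = params$kernel %||% "radial"
  )
  list(kind = "svm", fit = fit)
}

# ---- per-algorithm prediction ----------------------------------------------

.predict_algorithm <- function(fit, m, type = "class", classes = NULL) {
  prob <- switch(fit$kind,
    constant = {
      matrix(1, nrow(m), 1, dimnames = list(NULL, fit$class))
    },
    gnb = {
      ll <- vapply(seq_along(fit$levels), function(k) {
        mu <- fit$mu[[k]]; s2 <- fit$s2[[k]]
        log(fit$prior[k]) -
          0.5 * sum(log(2 * pi * s2)) -
          0.5 * rowSums(sweep(sweep(m, 2, mu), 2, sqrt(s2), "/")^2)
      }, numeric(nrow(m)))
      ll <- matrix(ll, nrow = nrow(m),
                   dimnames = list(NULL, fit$levels))
      ll <- exp(ll - apply(ll, 1, max))
      ll / rowSums(ll)
    },
    dt = {
      df <- as.data.frame(m)
      colnames(df) <- fit$safe_names
      predict(fit$fit, df, type = "prob")
    },
    rf = predict(fit$fit, data = m, num.threads = 1)$predictions,
    lr = {
      pr <- predict(fit$fit, newx = m, type = "response", s = fit$lambda)
      out <- pr[, , 1, drop = FALSE]
      dim(out) <- dim(pr)[1:2]
      colnames(out) <- dimnames(pr)[[2]]
      out
    },
    xgb = {
      pr <- predict(fit$fit, xgboost::xgb.DMatrix(m))
      if (is.matrix(pr)) {
        colnames(pr) <- fit$levels
        pr
      } else {
        matrix(pr, nrow = nrow(m), byrow = TRUE,
               dimnames = list(NULL, fit$levels))
      }
    },
    svm = {
      pr <- predict(fit$fit, m, probability = TRUE)
      attr(pr, "probabilities")
    }
  )
  if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1)
  # expand to the full class catalog in catalog order
  if (!is.null(classes)) {
    full <- matrix(0, nrow(prob), length(classes),
                   dimnames = list(NULL, classes))
    full[, colnames(prob)] <- prob
    prob <- full
  }
  prob <- prob / pmax(rowSums(prob), .Machine$double.eps)
  if (type == "prob") return(prob)
  colnames(prob)[max.col(prob, ties.method = "first")]
}
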