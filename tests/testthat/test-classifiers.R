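# Grid search, per-algorithm fitting, prediction contracts.

separable_toy <- function(n = 60, seed = 1) {
  set.seed(seed)
  x <- data.frame(f1 = c(rnorm(n / 2, 0), rnorm(n / 2, 8)),
                  f2 = rnorm(n))
  list(x = x, y = rep(c(1L, 2L), each = n / 2))
}

small_grid <- function(alg) {
  switch(alg,
    nb = list(var_smoothing = c(1e-9, 1e-6)),
    dt = list(max_depth = 10, criterion = "gini"),
    rf = list(n_estimators = 50),
    lr = list(C = c(1, 100), penalty = "l2"),
    xgb = list(max_depth = 6, n_estimators = 30),
    svm = list(C = 1, gamma = 0.5, kernel = "radial")
  )
}

test_that("every algorithm separates a linearly separable toy", {
  d <- separable_toy()
  for (alg in c("nb", "dt", "rf", "lr", "xgb", "svm")) {
    m <- grid_search_cv(d$x, d$y, model_spec(alg, grid = small_grid(alg)),
                        seed = 3)
    expect_gte(mean(m$fold_scores), 0.95)
    expect_equal(predict(m, d$x), d$y)
    # best_params drawn from the declared grid
    for (nm in names(m$best_params)) {
      expect_true(m$best_params[[nm]] %in% m$spec$grid[[nm]])
    }
    expect_length(m$fold_scores, m$spec$cv_folds)
  }
})

test_that("probability outputs are normalized and consistent with labels", {
  d <- separable_toy()
  for (alg in c("nb", "dt", "xgb")) {
    m <- grid_search_cv(d$x, d$y, model_spec(alg, grid = small_grid(alg)),
                        seed = 3)
    sc <- predict_scores(m, d$x)
    expect_equal(colnames(sc), m$classes)
    expect_true(all(abs(rowSums(sc) - 1) < 1e-9))
    argmax <- as.integer(colnames(sc)[max.col(sc, ties.method = "first")])
    expect_equal(argmax, predict(m, d$x))
  }
})

test_that("prediction aligns columns by name, not position", {
  d <- separable_toy()
  m <- grid_search_cv(d$x, d$y, model_spec("xgb", grid = small_grid("xgb")),
                      seed = 3)
  expect_identical(predict(m, d$x[, c("f2", "f1")]), predict(m, d$x))
  expect_error(predict(m, d$x[, "f1", drop = FALSE]),
               class = "ddihybrid_schema_error")
  extra <- d$x; extra$zzz <- 1
  err <- expect_error(predict(m, extra), class = "ddihybrid_schema_error")
  expect_match(conditionMessage(err), "zzz")
})

test_that("empty prediction input yields empty output", {
  d <- separable_toy()
  m <- grid_search_cv(d$x, d$y, model_spec("nb", grid = small_grid("nb")),
                      seed = 3)
  expect_identical(predict(m, d$x[0, ]), integer())
  expect_equal(nrow(predict_scores(m, d$x[0, ])), 0)
})

test_that("degenerate one-class training predicts that class with score 1", {
  x <- data.frame(f1 = rnorm(10), f2 = rnorm(10))
  y <- rep(4L, 10)
  m <- grid_search_cv(x, y, model_spec("nb", grid = small_grid("nb")),
                      seed = 1)
  expect_equal(predict(m, x), rep(4L, 10))
  sc <- predict_scores(m, x)
  expect_true(all(sc[, "4"] == 1))
})

test_that("grid search is deterministic given seed and data", {
  d <- separable_toy()
  spec <- model_spec("rf", grid = list(n_estimators = c(30, 50)))
  m1 <- grid_search_cv(d$x, d$y, spec, seed = 11)
  m2 <- grid_search_cv(d$x, d$y, spec, seed = 11)
  expect_identical(m1$best_params, m2$best_params)
  expect_identical(m1$cv_results, m2$cv_results)
  expect_identical(predict(m1, d$x), predict(m2, d$x))
})

test_that("folds are stratified, exhaustive and free of leakage", {
  set.seed(5)
  x <- data.frame(f1 = rnorm(50), f2 = rnorm(50))
  y <- rep(c(1L, 2L), times = c(30, 20))
  m <- grid_search_cv(x, y, model_spec("nb", grid = small_grid("nb"),
                                       cv_folds = 5), seed = 2)
  folds <- m$folds
  expect_length(folds, 50)
  expect_setequal(unique(folds), 1:5)
  for (f in 1:5) {  # per-fold class balance mirrors the data
    expect_equal(sum(y[folds == f] == 1), 6)
    expect_equal(sum(y[folds == f] == 2), 4)
  }
})

test_that("too-small classes for the fold count raise a helpful error", {
  x <- data.frame(f1 = rnorm(23), f2 = rnorm(23))
  y <- c(rep(1L, 20), rep(2L, 3))
  err <- expect_error(
    grid_search_cv(x, y, model_spec("nb", grid = small_grid("nb"),
                                    cv_folds = 5), seed = 1),
    class = "ddihybrid_error"
  )
  expect_match(conditionMessage(err), "filter_low_count_classes")
})

test_that("in-fold balancing is applied to training folds only", {
  set.seed(6)
  x <- data.frame(f1 = c(rnorm(40, 0), rnorm(10, 6)), f2 = rnorm(50))
  y <- rep(c(1L, 2L), times = c(40, 10))
  calls <- list()
  balance <- function(bx, by) {
    res <- smote_balance(bx, by, seed = 1)
    calls[[length(calls) + 1]] <<- nrow(bx)
    res
  }
  m <- grid_search_cv(x, y, model_spec("nb", grid = list(var_smoothing = 1e-9),
                                       cv_folds = 5), seed = 2,
                      balance = balance)
  # 5 training folds of 40 rows each, then the full 50-row refit
  expect_equal(unlist(calls), c(rep(40, 5), 50))
})

test_that("in-package Gaussian NB agrees with an independent implementation", {
  set.seed(9)
  x <- data.frame(f1 = c(rnorm(40, 0), rnorm(40, 2)),
                  f2 = c(rnorm(40, 1), rnorm(40, -1)))
  y <- rep(c(1L, 2L), each = 40)
  m <- grid_search_cv(x, y, model_spec("nb", grid = list(var_smoothing = 0)),
                      seed = 1)
  ref <- e1071::naiveBayes(x, factor(y))
  expect_equal(mean(predict(m, x) == as.integer(as.character(
    predict(ref, x)))), 1)
  p1 <- predict_scores(m, x)
  p2 <- predict(ref, x, type = "raw")
  expect_equal(unname(p1), unname(p2), tolerance = 1e-4)
})

test_that("tidy and glance summarise the search", {
  d <- separable_toy()
  m <- grid_search_cv(d$x, d$y,
                      model_spec("nb", grid = list(var_smoothing = c(1e-9, 1e-6))),
                      seed = 3)
  td <- tidy(m)
  expect_equal(nrow(td), 2)
  expect_true(all(c("var_smoothing", "mean_score") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$algorithm, "nb")
  expect_equal(gl$cv_folds, 5)
})
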