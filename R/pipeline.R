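# End-to-end pipeline: (simulate | load) -> featurize -> select -> balance
# -> train -> evaluate, with one global seed fanned out to the stages by
# fixed offsets and all artifacts written as CSV/JSON.

.stage_offsets <- c(simulate = 1L, split = 2L, select = 3L, balance = 4L,
                    train = 5L)

.derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 1000L * .stage_offsets[[stage]]) %% 2^31)
}

.default_pipeline_config <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    data = list(source = "simulate", n_drugs = 400, n_pairs = 5000,
                substrate_prob = 0.35, inhibitor_prob = 0.12,
                inducer_prob = 0.08, label_noise = 0.05, n_classes = 19,
                class_decay = 0.75),
    features = list(mode = "cross_product", scale = FALSE),
    filter = list(min_class_count = 50),
    split = list(train_fraction = 0.7),
    select = list(k = 94, num_trees = 500),
    balance = list(method = "smote", k_neighbors = 5),
    model = list(algorithm = "xgb", grid = NULL, cv_folds = 5,
                 scoring = "macro_f1")
  )
}

#' Quickstart pipeline configuration
#'
#' A small simulated run (150 drugs, 1500 pairs, reduced gradient-boosting
#' grid) that completes in a couple of minutes on one CPU; a template to
#' edit for real runs.
#'
#' @param seed Global seed.
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
quickstart_config <- function(seed = 7L) {
  cfg <- .default_pipeline_config()
  cfg$seed <- seed
  cfg$data$n_drugs <- 150
  cfg$data$n_pairs <- 1500
  cfg$filter$min_class_count <- 10
  cfg$select$num_trees <- 300
  cfg$model$grid <- list(max_depth = c(6, 10), n_estimators = 150,
                         max_features = "auto", min_samples_leaf = 1)
  cfg
}

.validate_config <- function(config) {
  base <- .default_pipeline_config()
  for (key in c("seed", "data")) {
    if (is.null(config[[key]])) {
      abort(paste0("pipeline config is missing required key '", key, "'"),
            class = "ddihybrid_config_error")
    }
  }
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    abort(paste0("unknown pipeline config key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "ddihybrid_config_error")
  }
  cfg <- utils::modifyList(base, config)
  if (identical(cfg$data$source, "files")) {
    for (key in c("drugs", "pairs")) {
      if (is.null(cfg$data[[key]])) {
        abort(paste0("pipeline config data source 'files' requires key '",
                     key, "'"), class = "ddihybrid_config_error")
      }
    }
  } else if (!identical(cfg$data$source, "simulate")) {
    abort("pipeline config data$source must be 'simulate' or 'files'",
          class = "ddihybrid_config_error")
  }
  cfg
}

#' Run the full DDI-type prediction pipeline
#'
#' Executes simulate-or-load, low-count class filtering, a stratified
#' 70/30 split, chemical-feature computation and consensus selection on the
#' training split only, hybrid assembly with the 12 CYP interaction
#' features, in-fold oversampling, cross-validated grid search, and
#' held-out evaluation.  Every stage logs its seed and row/column counts.
#'
#' @param config Nested configuration list (see [quickstart_config()]) or
#'   the path of a YAML file holding one.
#' @param quiet Suppress stage messages.
#' @return A `ddi_pipeline_result` list: `config`, `drugs`, `pairs`,
#'   `split`, `selected` (feature names), `selection` (report tibble),
#'   `model`, `metrics`, `test_scores`, `test_pred`.
#' @export
run_pipeline <- function(config = quickstart_config(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .validate_config(config)
  say <- function(...) if (!quiet) message("[ddihybrid] ", ...)

  # --- data ------------------------------------------------------------
  if (identical(cfg$data$source, "simulate")) {
    sim <- simulation_config(
      n_drugs = cfg$data$n_drugs, n_pairs = cfg$data$n_pairs,
      substrate_prob = cfg$data$substrate_prob,
      inhibitor_prob = cfg$data$inhibitor_prob,
      inducer_prob = cfg$data$inducer_prob,
      label_noise = cfg$data$label_noise,
      n_classes = cfg$data$n_classes, class_decay = cfg$data$class_decay,
      seed = .derive_seed(cfg$seed, "simulate")
    )
    drugs <- generate_drug_library(sim)
    descriptors <- compute_descriptors(drugs)
    pairs <- generate_ddi_dataset(drugs, sim, descriptors)
    say("simulated ", nrow(drugs), " drugs / ", nrow(pairs),
        " pairs (seed ", sim$seed, ")")
  } else {
    drugs <- read_drug_table(cfg$data$drugs)
    pairs <- read_ddi_table(cfg$data$pairs, drugs = drugs)
    descriptors <- compute_descriptors(drugs)
    say("loaded ", nrow(drugs), " drugs / ", nrow(pairs), " pairs")
  }
  if (isTRUE(cfg$features$scale)) {
    num <- setdiff(names(descriptors), "drug_id")
    descriptors[num] <- lapply(descriptors[num], function(v) {
      s <- sd(v)
      if (s > 0) (v - mean(v)) / s else v * 0
    })
  }

  pairs <- filter_low_count_classes(pairs, cfg$filter$min_class_count)
  say(nrow(pairs), " pairs after class cutoff >= ",
      cfg$filter$min_class_count)

  split_seed <- .derive_seed(cfg$seed, "split")
  split <- stratified_split(pairs, cfg$split$train_fraction, split_seed)
  say("split ", nrow(split$train), "/", nrow(split$test),
      " train/test (seed ", split_seed, ")")

  # --- chemical features + selection (training split only) -------------
  mode <- cfg$features$mode
  chem_train <- pair_feature_matrix(split$train, descriptors, mode)
  x_chem_train <- chem_train[, -(1:2)]
  sel_seed <- .derive_seed(cfg$seed, "select")
  forest <- rank_by_forest_importance(x_chem_train, split$train$label,
                                      seed = sel_seed,
                                      num_trees = cfg$select$num_trees)
  univ <- rank_by_univariate_score(x_chem_train, split$train$label)
  selected <- consensus_select(list(forest, univ), k = cfg$select$k)
  report <- selection_report(forest, univ, selected)
  say("selected ", length(selected), " of ", ncol(x_chem_train),
      " chemical features (seed ", sel_seed, ")")

  # --- hybrid rows ------------------------------------------------------
  hybrid <- function(part) {
    chem <- pair_feature_matrix(part, descriptors, mode)
    cyp <- cyp_interaction_features(part, drugs)
    bind_cols(chem[, selected], cyp[, -(1:2)])
  }
  x_train <- hybrid(split$train)
  x_test <- hybrid(split$test)
  say("hybrid feature width: ", ncol(x_train))

  # --- balance + train --------------------------------------------------
  bal_seed <- .derive_seed(cfg$seed, "balance")
  balance_fn <- if (identical(cfg$balance$method, "none")) NULL else {
    function(x, y) smote_balance(
      x, y, k_neighbors = cfg$balance$k_neighbors,
      seed = bal_seed, method = cfg$balance$method
    )
  }
  grid <- cfg$model$grid %||% default_grid(cfg$model$algorithm)
  spec <- model_spec(cfg$model$algorithm, grid = grid,
                     cv_folds = cfg$model$cv_folds,
                     scoring = cfg$model$scoring)
  train_seed <- .derive_seed(cfg$seed, "train")
  say("training ", cfg$model$algorithm, " over ",
      prod(lengths(spec$grid)), " grid point(s), ", spec$cv_folds,
      "-fold CV (seed ", train_seed, ")")
  model <- grid_search_cv(x_train, split$train$label, spec,
                          seed = train_seed, balance = balance_fn)

  # --- evaluate ---------------------------------------------------------
  test_pred <- predict(model, x_test)
  test_scores <- predict_scores(model, x_test)
  metrics <- evaluate_predictions(split$test$label, test_pred,
                                  scores = test_scores,
                                  classes = as.integer(model$classes))
  say("held-out accuracy ", round(metrics$summary$accuracy, 3),
      ", macro-F1 ", round(metrics$summary$macro_f1, 3))

  result <- structure(
    list(config = cfg, drugs = drugs, pairs = pairs, split = split,
         descriptors = descriptors, selected = selected,
         selection = report, model = model, metrics = metrics,
         test_scores = test_scores, test_pred = test_pred),
    class = "ddi_pipeline_result"
  )
  if (!is.null(cfg$output_dir)) .write_artifacts(result, cfg$output_dir)
  result
}

.write_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_drug_table(result$drugs, file.path(dir, "drugs.csv"))
  write_ddi_table(result$pairs, file.path(dir, "pairs.csv"))
  write_label_catalog(label_catalog(), file.path(dir, "labels.csv"))
  readr::write_csv(result$selection, file.path(dir, "selection_report.csv"))
  readr::write_csv(tidy(result$metrics), file.path(dir, "metrics_per_class.csv"))
  readr::write_csv(
    roc_points(result$split$test$label, result$test_scores,
               as.integer(result$model$classes)),
    file.path(dir, "roc_points.csv")
  )
  jsonlite::write_json(
    list(summary = as.list(glance(result$metrics)),
         best_params = result$model$best_params,
         algorithm = result$model$spec$algorithm,
         seed = result$config$seed),
    file.path(dir, "metrics_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  saveRDS(result$model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @export
print.ddi_pipeline_result <- function(x, ...) {
  cat("<ddi_pipeline_result>\n")
  cat("  drugs:", nrow(x$drugs), " pairs:", nrow(x$pairs), "\n")
  cat("  features:", length(x$selected), "chemical +",
      length(cyp_enzymes()), "CYP\n")
  cat("  model:", x$model$spec$algorithm, "\n")
  print(x$metrics$summary)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `ddi_pipeline_result`.
#' @param ... Unused.
#' @export
glance.ddi_pipeline_result <- function(x, ...) {
  bind_cols(tibble(algorithm = x$model$spec$algorithm), x$metrics$summary)
}
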