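# Consensus feature selection on the chemical interaction features.
#
# Two rankings are computed on training data only -- random-forest impurity
# importance and a univariate one-way ANOVA F score -- and the selected set
# is the consensus of both: the smallest top-m lists of each ranking whose
# intersection holds at least k features, truncated to k by mean rank.

.as_feature_matrix <- function(x) {
  num <- vapply(x, is.numeric, logical(1))
  m <- as.matrix(x[, num, drop = FALSE])
  if (is.null(colnames(m)) || anyDuplicated(colnames(m))) {
    abort("feature columns must carry unique names",
          class = "ddihybrid_error")
  }
  m
}

.new_ranking <- function(method, feature, score) {
  feature <- unname(feature)
  score <- unname(score)
  # ties broken deterministically: score descending, then name ascending
  ord <- order(-score, feature)
  structure(
    tibble(feature = feature[ord], score = score[ord],
           rank = seq_along(ord)),
    method = method, class = c("ddi_ranking", "tbl_df", "tbl", "data.frame")
  )
}

#' Rank features by random-forest importance
#'
#' Impurity-based (Gini) importance from a classification forest; scores
#' are keyed to feature names, so column order does not matter.
#'
#' @param x Data frame or matrix of numeric features (named columns).
#' @param y Class labels (coerced to factor; at least two classes).
#' @param seed Integer seed (the forest is deterministic given it).
#' @param num_trees Number of trees (default 500).
#' @return A `ddi_ranking` tibble: `feature`, `score`, `rank`, sorted by
#'   descending score with lexicographic tie-break.
#' @export
rank_by_forest_importance <- function(x, y, seed = 1L, num_trees = 500) {
  m <- .as_feature_matrix(x)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) {
    abort("y must contain at least two classes", class = "ddihybrid_error")
  }
  df <- as.data.frame(m)
  colnames(df) <- colnames(m)  # keep non-syntactic feature names intact
  df$.outcome <- droplevels(y)
  fit <- ranger::ranger(
    dependent.variable.name = ".outcome", data = df,
    num.trees = num_trees, importance = "impurity",
    seed = seed, num.threads = 1, verbose = FALSE
  )
  imp <- fit$variable.importance
  .new_ranking("forest_importance", names(imp), unname(imp))
}

#' Rank features by univariate ANOVA F score
#'
#' One-way analysis-of-variance F statistic of each feature against the
#' class labels (the "best k by fit" univariate selector).  Within-class
#' variance is floored at a tiny fraction of the total variance so that
#' perfectly separating features receive a large finite score; constant
#' features score 0.
#'
#' @inheritParams rank_by_forest_importance
#' @return A `ddi_ranking` tibble.
#' @export
rank_by_univariate_score <- function(x, y) {
  m <- .as_feature_matrix(x)
  y <- droplevels(factor(y))
  k <- nlevels(y)
  if (k < 2) abort("y must contain at least two classes",
                   class = "ddihybrid_error")
  n <- nrow(m)
  grand <- colMeans(m)
  ssb <- numeric(ncol(m))
  ssw <- numeric(ncol(m))
  for (lev in levels(y)) {
    rows <- y == lev
    mu <- colMeans(m[rows, , drop = FALSE])
    ssb <- ssb + sum(rows) * (mu - grand)^2
    ssw <- ssw + colSums(sweep(m[rows, , drop = FALSE], 2, mu)^2)
  }
  tot <- ssb + ssw
  floor_ <- pmax(tot, 1) * 1e-12
  f <- (ssb / (k - 1)) / pmax(ssw / pmax(n - k, 1), floor_)
  f[ssb <= 0] <- 0
  .new_ranking("univariate_f", colnames(m), f)
}

#' Consensus selection of top-k features
#'
#' Finds the smallest m such that the top-m features of every ranking share
#' at least `k` features, then returns that intersection ordered by mean
#' rank (ties broken lexicographically) and truncated to `k`.
#'
#' @param rankings List of `ddi_ranking` tibbles over the same feature
#'   universe.
#' @param k Number of features to select (default 94).
#' @return Character vector of `k` feature names.
#' @export
consensus_select <- function(rankings, k = 94) {
  stopifnot(length(rankings) >= 1)
  universe <- rankings[[1]]$feature
  for (r in rankings) {
    if (!setequal(r$feature, universe)) {
      abort("rankings do not share the same feature universe",
            class = "ddihybrid_error")
    }
  }
  n <- length(universe)
  if (k > n) {
    abort(sprintf("k = %d exceeds the number of features (%d)", k, n),
          class = "ddihybrid_error")
  }
  tops <- lapply(rankings, function(r) r$feature)  # already rank-ordered
  common <- character()
  for (m in seq(k, n)) {
    common <- Reduce(intersect, lapply(tops, head, m))
    if (length(common) >= k) break
  }
  mean_rank <- rowMeans(vapply(rankings, function(r) {
    match(common, r$feature)
  }, numeric(length(common))))
  common[order(mean_rank, common)][seq_len(k)]
}

#' Selection report
#'
#' Cross-tabulates both ranking scores with the selected flag; written by
#' the pipeline as `selection_report.csv`.
#'
#' @param forest,univariate `ddi_ranking` tibbles.
#' @param selected Character vector from [consensus_select()].
#' @return Tibble: `feature`, `forest_score`, `forest_rank`,
#'   `univariate_score`, `univariate_rank`, `selected`.
#' @export
selection_report <- function(forest, univariate, selected) {
  tibble(feature = forest$feature,
         forest_score = forest$score,
         forest_rank = forest$rank) |>
    left_join(
      tibble(feature = univariate$feature,
             univariate_score = univariate$score,
             univariate_rank = univariate$rank),
      by = "feature"
    ) |>
    mutate(selected = .data$feature %in% selected) |>
    arrange(dplyr::desc(.data$selected),
            .data$forest_rank + .data$univariate_rank)
}
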