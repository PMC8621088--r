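# Multiclass evaluation: one-vs-rest confusion counts, precision / recall /
# F1 / accuracy, and one-vs-rest ROC/AUC with midrank tie handling.

#' One-vs-rest confusion counts
#'
#' For every class `c`, counts TP, FP, FN, TN treating `c` as positive and
#' all other classes as negative; the four counts sum to the total sample
#' count for each class.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param classes Class universe (default: classes observed in either
#'   vector, sorted).
#' @return Tibble: `class`, `tp`, `fp`, `fn`, `tn`, `support`.
#' @export
#' @examples
#' confusion_counts(c(1, 1, 2), c(1, 2, 2))
confusion_counts <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred differ in length",
          class = "ddihybrid_dimension_error")
  }
  classes <- classes %||% sort(unique(c(y_true, y_pred)))
  n <- length(y_true)
  rows <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    tibble(class = cl, tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn,
           support = tp + fn)
  })
  bind_rows(rows)
}

#' Metrics from one-vs-rest counts
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and their harmonic
#' mean F1, plus overall accuracy and macro/micro averages.  A zero
#' denominator yields a 0 metric with the `zero_division` flag set.  Macro
#' averages run over classes with positive support.
#'
#' @param counts Output of [confusion_counts()].
#' @return A `ddi_metrics` object: list with `per_class` tibble
#'   (class, precision, recall, f1, support, zero_division) and `summary`
#'   tibble (accuracy, macro/micro precision, recall, f1).
#' @export
metrics_from_counts <- function(counts) {
  per <- counts |>
    mutate(
      precision = ifelse(.data$tp + .data$fp > 0,
                         .data$tp / (.data$tp + .data$fp), 0),
      recall = ifelse(.data$tp + .data$fn > 0,
                      .data$tp / (.data$tp + .data$fn), 0),
      zero_division = (.data$tp + .data$fp == 0) | (.data$tp + .data$fn == 0),
      f1 = ifelse(.data$precision + .data$recall > 0,
                  2 * .data$precision * .data$recall /
                    (.data$precision + .data$recall), 0)
    ) |>
    select("class", "precision", "recall", "f1", "support", "zero_division")
  n <- sum(counts$support)
  present <- per$support > 0
  acc <- if (n > 0) sum(counts$tp) / n else 0
  summary <- tibble(
    accuracy = acc,
    macro_precision = mean(per$precision[present]),
    macro_recall = mean(per$recall[present]),
    macro_f1 = mean(per$f1[present]),
    micro_precision = acc,  # single-label multiclass: micro P = R = accuracy
    micro_recall = acc,
    micro_f1 = acc
  )
  structure(list(per_class = per, summary = summary), class = "ddi_metrics")
}

#' Evaluate predictions in one call
#'
#' @param y_true,y_pred Label vectors.
#' @param scores Optional per-class score matrix (columns in class order)
#'   for ROC/AUC.
#' @param classes Class universe.
#' @return A `ddi_metrics` object; when `scores` is given, with an `auc`
#'   tibble and `macro_auc` in `summary`.
#' @export
evaluate_predictions <- function(y_true, y_pred, scores = NULL,
                                 classes = NULL) {
  classes <- classes %||% sort(unique(c(y_true, y_pred)))
  out <- metrics_from_counts(confusion_counts(y_true, y_pred, classes))
  if (!is.null(scores)) {
    auc <- roc_auc_ovr(y_true, scores, classes)
    out$auc <- auc
    out$summary$macro_auc <- attr(auc, "macro_auc")
  }
  out
}

#' @export
print.ddi_metrics <- function(x, ...) {
  cat("Multiclass metrics over", nrow(x$per_class), "classes\n")
  print(x$summary)
  cat("\nPer-class:\n")
  print(x$per_class, n = nrow(x$per_class))
  invisible(x)
}

#' @rdname metrics_from_counts
#' @param x A `ddi_metrics` object.
#' @param ... Unused.
#' @export
tidy.ddi_metrics <- function(x, ...) {
  out <- x$per_class
  if (!is.null(x$auc)) out <- left_join(out, x$auc, by = "class")
  out
}

#' @rdname metrics_from_counts
#' @export
glance.ddi_metrics <- function(x, ...) x$summary

#' One-vs-rest ROC AUC
#'
#' Area under the ROC curve for each class against the rest, computed by
#' the rank (Mann-Whitney) formula, which equals trapezoidal integration
#' with midrank tie handling.  Classes absent from `y_true` get `NA`.
#'
#' @param y_true Label vector.
#' @param scores Numeric matrix, one column per class in `classes` order.
#' @param classes Class universe (default: column names of `scores` or
#'   sorted observed labels).
#' @return Tibble `class`, `auc`, with attribute `macro_auc` (mean over
#'   defined classes).
#' @export
roc_auc_ovr <- function(y_true, scores, classes = NULL) {
  scores <- as.matrix(scores)
  classes <- classes %||% colnames(scores) %||% sort(unique(y_true))
  if (ncol(scores) != length(classes)) {
    abort("scores must have one column per class",
          class = "ddihybrid_dimension_error")
  }
  aucs <- vapply(seq_along(classes), function(k) {
    pos <- y_true == classes[k]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(scores[, k])  # midranks under ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  out <- tibble(class = classes, auc = aucs)
  attr(out, "macro_auc") <- mean(aucs, na.rm = TRUE)
  out
}

#' ROC curve points
#'
#' False/true positive rates for each one-vs-rest binarization, ordered by
#' descending score threshold; suitable for plotting or CSV export.
#'
#' @inheritParams roc_auc_ovr
#' @return Tibble `class`, `fpr`, `tpr`.
#' @export
roc_points <- function(y_true, scores, classes = NULL) {
  scores <- as.matrix(scores)
  classes <- classes %||% colnames(scores) %||% sort(unique(y_true))
  bind_rows(lapply(seq_along(classes), function(k) {
    pos <- y_true == classes[k]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NULL)
    ord <- order(scores[, k], decreasing = TRUE)
    tp <- cumsum(pos[ord])
    fp <- cumsum(!pos[ord])
    keep <- !duplicated(scores[ord, k], fromLast = TRUE)  # one point per threshold
    tibble(class = classes[k], fpr = c(0, fp[keep] / n0),
           tpr = c(0, tp[keep] / n1))
  }))
}

# internal scorer used by grid search
.macro_f1 <- function(y_true, y_pred) {
  metrics_from_counts(
    confusion_counts(y_true, y_pred, sort(unique(y_true)))
  )$summary$macro_f1
}

.accuracy <- function(y_true, y_pred) mean(y_true == y_pred)
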