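# ggplot2 views of the result objects.

#' Plot per-class metrics
#'
#' Bar chart of precision, recall and F1 per class.
#'
#' @param object A `ddi_metrics` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ddi_metrics <- function(object, ...) {
  df <- object$per_class |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$class), y = .data$value, fill = .data$metric
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "interaction class", y = NULL,
                  title = "Per-class precision / recall / F1") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot one-vs-rest ROC curves
#'
#' @param y_true Label vector.
#' @param scores Per-class score matrix (catalog order).
#' @param classes Class universe.
#' @return A ggplot with one curve per class.
#' @export
plot_roc_curves <- function(y_true, scores, classes = NULL) {
  pts <- roc_points(y_true, scores, classes)
  auc <- roc_auc_ovr(y_true, scores, classes)
  ggplot2::ggplot(pts, ggplot2::aes(
    x = .data$fpr, y = .data$tpr, colour = factor(.data$class)
  )) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      colour = "class",
      title = sprintf("One-vs-rest ROC (macro AUC %.3f)",
                      attr(auc, "macro_auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the class-size distribution of a pair table
#'
#' Descending bar chart of class counts; the long tail this shows is why
#' the pipeline applies a low-count cutoff and oversampling.
#'
#' @param pairs Tibble with a `label` column.
#' @return A ggplot.
#' @export
plot_class_distribution <- function(pairs) {
  df <- pairs |> count(.data$label) |> arrange(dplyr::desc(.data$n))
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "interaction class", y = "drug pairs",
                  title = "Class-size distribution") +
    ggplot2::theme_minimal()
}

#' @rdname run_pipeline
#' @param object A `ddi_pipeline_result`.
#' @export
autoplot.ddi_pipeline_result <- function(object, ...) {
  autoplot(object$metrics)
}
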