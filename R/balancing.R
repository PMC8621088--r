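# Minority-class oversampling.
#
# SMOTE synthesises minority-class rows as convex combinations
# x + u * (x_nn - x), u ~ U(0, 1), of a row and one of its k nearest
# same-class neighbours, until every class matches the majority count.
# `method = "duplicate"` replaces interpolation with plain resampling of
# existing minority rows (random oversampling).

#' Oversample minority classes
#'
#' Balances a multiclass training set so every class count equals the
#' majority class count.  Original rows are preserved verbatim and come
#' first; synthetic rows follow.  Classes with a single member fall back to
#' duplication with a warning (no neighbour to interpolate towards).
#'
#' @param x Data frame or matrix of numeric features.
#' @param y Class labels (factor or coercible).
#' @param k_neighbors Number of same-class nearest neighbours considered
#'   (default 5); automatically reduced to class size - 1 where needed.
#' @param seed Integer seed; results are deterministic given it.
#' @param method `"smote"` (interpolation, default) or `"duplicate"`
#'   (random oversampling).
#' @return List with `x` (tibble, original rows then synthetic rows) and
#'   `y` (factor of matching length).
#' @export
#' @examples
#' x <- data.frame(a = c(1:6, 100, 101), b = c(1:6, 100, 101) / 2)
#' y <- c(rep("big", 6), rep("small", 2))
#' smote_balance(x, y, seed = 7)
smote_balance <- function(x, y, k_neighbors = 5, seed = 1L,
                          method = c("smote", "duplicate")) {
  method <- match.arg(method)
  m <- if (is.matrix(x)) x else .as_feature_matrix(x)
  y <- droplevels(factor(y))
  stopifnot(nrow(m) == length(y))
  counts <- table(y)
  target <- max(counts)
  syn_x <- list()
  syn_y <- list()
  withr::with_seed(seed, {
    for (lev in names(counts)) {
      need <- target - counts[[lev]]
      if (need == 0) next
      rows <- which(y == lev)
      xm <- m[rows, , drop = FALSE]
      if (length(rows) == 1 || method == "duplicate") {
        if (length(rows) == 1 && method == "smote") {
          warn(paste0("class '", lev, "' has a single sample; ",
                      "falling back to duplication"))
        }
        pick <- sample.int(length(rows), need, replace = TRUE)
        syn <- xm[pick, , drop = FALSE]
      } else {
        k <- min(k_neighbors, length(rows) - 1)
        d <- as.matrix(stats::dist(xm))
        diag(d) <- Inf
        nn <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
          order(d[i, ])[seq_len(k)]
        }))
        base <- sample.int(length(rows), need, replace = TRUE)
        nbr_choice <- sample.int(k, need, replace = TRUE)
        u <- runif(need)
        nbr <- nn[cbind(base, nbr_choice)]
        syn <- xm[base, , drop = FALSE] +
          u * (xm[nbr, , drop = FALSE] - xm[base, , drop = FALSE])
      }
      syn_x[[lev]] <- syn
      syn_y[[lev]] <- rep(lev, need)
    }
  })
  out_x <- rbind(m, do.call(rbind, unname(syn_x)))
  out_y <- factor(c(as.character(y), unlist(unname(syn_y))),
                  levels = levels(y))
  rownames(out_x) <- NULL
  list(x = as_tibble(out_x), y = out_y)
}
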