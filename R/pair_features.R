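# Pairwise combination operators turning two per-drug descriptor vectors
# (victim A, perpetrator B) into one interaction feature vector.
#
# Three operators are supported:
#   * cross_product: every product fa[i] * fb[j], k = (i - 1) * p + j
#     (row-major, victim index outer) -> p^2 features
#   * concat: (fa, fb) -> 2p features
#   * sum_product: all elementwise sums, then all elementwise products
#     (blocked layout) -> 2p features

.check_pairable <- function(fa, fb) {
  if (length(fa) != length(fb)) {
    abort(sprintf("descriptor vectors differ in length (%d vs %d)",
                  length(fa), length(fb)),
          class = "ddihybrid_dimension_error")
  }
  if (!is.null(names(fa)) && !is.null(names(fb)) &&
      !identical(names(fa), names(fb))) {
    abort("descriptor vectors have different name order",
          class = "ddihybrid_dimension_error")
  }
}

.feat_names <- function(nms, mode) {
  switch(mode,
    cross_product = as.vector(t(outer(nms, nms, function(a, b)
      paste0("A:", a, "*B:", b)))),
    concat = c(paste0("A:", nms), paste0("B:", nms)),
    sum_product = c(paste0("A+B:", nms), paste0("A*B:", nms))
  )
}

#' Cross-product interaction features
#'
#' Forms all pairwise products between the victim's and perpetrator's
#' descriptor values: feature `k = (i - 1) * p + j` is `fa[i] * fb[j]`
#' (row-major, victim index outer).  With the default 60-descriptor set this
#' yields 3600 features per pair, the richest of the three operators.
#'
#' @param fa,fb Named numeric descriptor vectors of equal length and name
#'   order (victim first, perpetrator second).
#' @return Named numeric vector of length `p^2`; names have the form
#'   `"A:<name_i>*B:<name_j>"`.
#' @seealso [concat_features()], [sum_product_features()],
#'   [pair_feature_matrix()]
#' @export
#' @examples
#' cross_product_features(c(x = 2, y = 3), c(x = 5, y = 7))
cross_product_features <- function(fa, fb) {
  .check_pairable(fa, fb)
  p <- length(fa)
  out <- as.vector(t(outer(fa, fb)))  # row-major: out[(i-1)*p + j] = fa[i]*fb[j]
  nms <- names(fa) %||% paste0("d", seq_len(p))
  names(out) <- .feat_names(nms, "cross_product")
  out
}

#' Concatenation interaction features
#'
#' Concatenates the two descriptor vectors: `(fa, fb)`, length `2p`.
#'
#' @inheritParams cross_product_features
#' @return Named numeric vector of length `2p`.
#' @export
#' @examples
#' concat_features(c(x = 2, y = 3), c(x = 5, y = 7))
concat_features <- function(fa, fb) {
  .check_pairable(fa, fb)
  nms <- names(fa) %||% paste0("d", seq_along(fa))
  setNames(c(unname(fa), unname(fb)), .feat_names(nms, "concat"))
}

#' Sum-and-product interaction features
#'
#' Blocked layout: all elementwise sums `fa[i] + fb[i]` in positions
#' `1..p`, then all elementwise products `fa[i] * fb[i]` in positions
#' `p+1..2p`.
#'
#' @inheritParams cross_product_features
#' @return Named numeric vector of length `2p`.
#' @export
#' @examples
#' sum_product_features(c(x = 2, y = 3), c(x = 5, y = 7))
sum_product_features <- function(fa, fb) {
  .check_pairable(fa, fb)
  nms <- names(fa) %||% paste0("d", seq_along(fa))
  setNames(c(unname(fa) + unname(fb), unname(fa) * unname(fb)),
           .feat_names(nms, "sum_product"))
}

#' Pair-level chemical interaction feature matrix
#'
#' Applies one combination operator to every ordered (victim, perpetrator)
#' pair, looking descriptor vectors up by drug id.
#'
#' @param pairs Data frame with columns `victim_id` and `perpetrator_id`.
#' @param descriptors Output of [compute_descriptors()]: one row per drug.
#' @param mode One of `"cross_product"`, `"concat"`, `"sum_product"`.
#' @return A tibble: `victim_id`, `perpetrator_id`, then one column per
#'   interaction feature.
#' @export
pair_feature_matrix <- function(pairs, descriptors,
                                mode = c("cross_product", "concat",
                                         "sum_product")) {
  mode <- match.arg(mode)
  stopifnot(all(c("victim_id", "perpetrator_id") %in% names(pairs)))
  missing_ids <- setdiff(
    unique(c(pairs$victim_id, pairs$perpetrator_id)), descriptors$drug_id
  )
  if (length(missing_ids)) {
    abort(paste0("pairs reference drugs absent from the descriptor table: ",
                 paste(head(missing_ids, 5), collapse = ", ")),
          class = "ddihybrid_schema_error")
  }
  dm <- as.matrix(descriptors[, setdiff(names(descriptors), "drug_id")])
  rownames(dm) <- descriptors$drug_id
  A <- dm[pairs$victim_id, , drop = FALSE]
  B <- dm[pairs$perpetrator_id, , drop = FALSE]
  p <- ncol(dm)
  nms <- .feat_names(colnames(dm), mode)
  out <- switch(mode,
    cross_product = {
      M <- matrix(0, nrow(A), p^2)
      for (i in seq_len(p)) M[, (i - 1L) * p + seq_len(p)] <- A[, i] * B
      M
    },
    concat = cbind(A, B),
    sum_product = cbind(A + B, A * B)
  )
  colnames(out) <- nms
  bind_cols(
    tibble(victim_id = pairs$victim_id, perpetrator_id = pairs$perpetrator_id),
    as_tibble(out)
  )
}
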