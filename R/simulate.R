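# Synthetic drug libraries and directional DDI datasets.
#
# The generator plants a documented decision rule so that every pipeline
# stage has recoverable signal:
#   * CYP-silent pairs are classified by chemistry: quartiles of the
#     victim x perpetrator molecular-weight product crossed with a
#     (within-quartile) median split of the Randic connectivity product
#     map to classes 1-7 (the head of the
#     class-size profile, mirroring the dominance of chemical interaction
#     features in this problem);
#   * pairs whose CYP interaction vector is nonzero take a class from the
#     mechanism families -- the first nonzero component (panel order)
#     selects an enzyme group (two enzymes per group, six groups), and its
#     sign selects inhibition (classes 8-13, increased victim exposure) or
#     induction (classes 14-19, decreased exposure).
# The observed label is then flipped to a uniformly drawn other class with
# probability `label_noise`, so the Bayes accuracy on generated data is
# 1 - noise * (K - 1) / K.  Class sizes follow a geometric decay profile.

# concatenation-safe SMILES fragment grammar: every chain fragment can be
# prefixed and suffixed by another fragment; terminals close the molecule
.frag_chain <- c(
  "C", "CC", "CCC", "CCO", "CCN", "COC", "CNC", "CS", "C=C",
  "c1ccccc1", "c1ccncc1", "C1CCCCC1", "C1CCNCC1", "C1CCOC1", "CC(=O)N"
)
.frag_terminal <- c(
  "C", "O", "N", "Cl", "F", "Br", "C#N", "C(=O)O", "OC", "C(C)C"
)

#' Simulation configuration
#'
#' Study conditions for the synthetic generator.  Defaults: per-enzyme
#' substrate probability 0.35, inhibitor 0.12, inducer 0.08; label noise
#' 0.05; 19 classes with geometric class-size decay factor 0.75.
#'
#' @param n_drugs Number of drugs in the library.
#' @param n_pairs Number of ordered (victim, perpetrator) pairs.
#' @param substrate_prob,inhibitor_prob,inducer_prob Per-enzyme role
#'   probabilities (`inhibitor_prob + inducer_prob <= 1`).
#' @param label_noise Probability of flipping a label to a uniform other
#'   class; must be in `[0, 0.5)`.
#' @param n_classes Number of interaction classes (default 19).
#' @param class_decay Geometric decay factor of target class sizes
#'   (default 0.75).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_drugs = 400, n_pairs = 5000,
                              substrate_prob = 0.35, inhibitor_prob = 0.12,
                              inducer_prob = 0.08, label_noise = 0.05,
                              n_classes = 19, class_decay = 0.75,
                              seed = 1L) {
  stopifnot(
    n_drugs >= 2, n_pairs >= 1,
    substrate_prob >= 0, substrate_prob <= 1,
    inhibitor_prob >= 0, inducer_prob >= 0,
    inhibitor_prob + inducer_prob <= 1,
    label_noise >= 0, label_noise < 0.5,
    n_classes >= 2, class_decay > 0, class_decay <= 1
  )
  structure(
    list(n_drugs = n_drugs, n_pairs = n_pairs,
         substrate_prob = substrate_prob, inhibitor_prob = inhibitor_prob,
         inducer_prob = inducer_prob, label_noise = label_noise,
         n_classes = as.integer(n_classes), class_decay = class_decay,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate a synthetic drug library
#'
#' Assembles valid SMILES from a fixed fragment grammar (one to three
#' chainable fragments plus a terminal) and samples an independent CYP
#' profile per drug: each enzyme is a substrate with `substrate_prob`, and
#' carries a perpetrator role with `inhibitor_prob` / `inducer_prob`.
#' Byte-identical output for a given seed.
#'
#' @param config A [simulation_config()].
#' @return Normalized drug tibble (`drug_id`, `smiles`, `sub_<enzyme>`,
#'   `perp_<enzyme>`), as [read_drug_table()] returns.
#' @export
#' @examples
#' lib <- generate_drug_library(simulation_config(n_drugs = 5, n_pairs = 4))
#' lib$smiles
generate_drug_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_drugs
  withr::with_seed(config$seed, {
    smiles <- vapply(seq_len(n), function(i) {
      k <- sample(1:3, 1)
      paste0(paste(sample(.frag_chain, k, replace = TRUE), collapse = ""),
             sample(.frag_terminal, 1))
    }, character(1))
    out <- tibble(
      drug_id = sprintf("D%05d", seq_len(n)),
      smiles = smiles
    )
    for (e in .cyp_panel) {
      out[[paste0("sub_", e)]] <-
        as.integer(runif(n) < config$substrate_prob)
      u <- runif(n)
      out[[paste0("perp_", e)]] <- ifelse(
        u < config$inhibitor_prob, "inhibitor",
        ifelse(u < config$inhibitor_prob + config$inducer_prob,
               "inducer", "none")
      )
    }
    out
  })
}

#' Names of the chemical features the planted rule uses
#'
#' The CYP-silent part of the synthetic decision rule is driven by the
#' molecular-weight product and the Randic connectivity (Chi1) product of
#' the pair; under
#' the given combination operator these correspond to specific interaction
#' feature names.  Feature-recovery checks test that consensus selection
#' finds them.
#'
#' @param mode Combination operator (only `"cross_product"` features carry
#'   the products directly).
#' @return Character vector of feature names.
#' @export
planted_rule_features <- function(mode = "cross_product") {
  stopifnot(identical(mode, "cross_product"))
  c("A:MW*B:MW", "A:Chi1*B:Chi1")
}

#' Generate a directional DDI dataset with a planted rule
#'
#' Labels every ordered pair of the library by the documented decision rule
#' (see the package vignette), then samples `n_pairs` pairs so that class
#' sizes follow the geometric decay profile, and finally flips each label
#' to a uniform other class with probability `label_noise`.
#'
#' @param drugs Drug library from [generate_drug_library()].
#' @param config The same [simulation_config()].
#' @param descriptors Optional precomputed [compute_descriptors()] output
#'   for `drugs` (computed on the fly otherwise).
#' @return Tibble `victim_id`, `perpetrator_id`, `label`, with attributes:
#'   `true_label` (pre-noise labels), `bayes_accuracy`
#'   (`1 - noise * (K-1)/K`), and `rule` (the fitted rule thresholds).
#' @export
generate_ddi_dataset <- function(drugs, config, descriptors = NULL) {
  stopifnot(inherits(config, "sim_config"), nrow(drugs) >= 2)
  n <- nrow(drugs)
  max_pairs <- n * (n - 1)
  if (config$n_pairs > max_pairs) {
    abort(sprintf("n_pairs = %d exceeds the %d ordered pairs of %d drugs",
                  config$n_pairs, max_pairs, n),
          class = "ddihybrid_error")
  }
  if (is.null(descriptors)) descriptors <- compute_descriptors(drugs)

  # label the full ordered-pair pool by the planted rule
  pool <- expand.grid(a = seq_len(n), b = seq_len(n))
  pool <- pool[pool$a != pool$b, ]
  enc <- encode_cyp_vectors(drugs)
  V <- as.matrix(enc[, paste0("victim_", .cyp_panel)])
  P <- as.matrix(enc[, paste0("perp_", .cyp_panel)])
  M <- V[pool$a, , drop = FALSE] * P[pool$b, , drop = FALSE]
  nz <- M != 0
  has_cyp <- rowSums(nz) > 0
  first <- max.col(nz, ties.method = "first")
  sign_first <- M[cbind(seq_len(nrow(M)), first)]
  group <- ceiling(first / 2)  # six two-enzyme groups in panel order

  mw <- descriptors$MW[match(drugs$drug_id, descriptors$drug_id)]
  chi1 <- descriptors$Chi1[match(drugs$drug_id, descriptors$drug_id)]
  mwp <- mw[pool$a] * mw[pool$b]
  rgp <- chi1[pool$a] * chi1[pool$b]
  silent <- !has_cyp
  mw_cuts <- stats::quantile(mwp[silent], c(0.25, 0.5, 0.75), names = FALSE)
  mw_bin <- findInterval(mwp, mw_cuts)            # 0..3
  # connectivity split within each MW bin, so the eight rule cells are
  # similarly available in the pool despite the two products being correlated
  rg_cuts <- vapply(0:3, function(b) {
    v <- rgp[silent & mw_bin == b]
    if (length(v)) stats::median(v) else stats::median(rgp[silent])
  }, numeric(1))
  rg_bin <- as.integer(rgp > rg_cuts[mw_bin + 1L]) # 0..1
  cell <- 2L * mw_bin + rg_bin                    # 0..7
  true <- integer(nrow(pool))
  true[silent] <- 1L + (cell[silent] %% 7L)
  true[has_cyp] <- ifelse(sign_first[has_cyp] > 0, 7L + group[has_cyp],
                          13L + group[has_cyp])
  true <- pmin(true, config$n_classes)

  # draw the target geometric class profile, then sample pairs per class
  K <- config$n_classes
  w <- config$class_decay^(seq_len(K) - 1)
  w <- w / sum(w)
  out_idx <- withr::with_seed(config$seed + 1L, {
    want <- as.integer(stats::rmultinom(1, config$n_pairs, w))
    picked <- integer(0)
    short <- 0L
    for (k in seq_len(K)) {
      avail <- which(true == k)
      take <- min(want[k], length(avail))
      short <- short + want[k] - take
      if (take > 0) picked <- c(picked, sample(avail, take))
    }
    if (short > 0) {
      rest <- setdiff(seq_len(nrow(pool)), picked)
      picked <- c(picked, sample(rest, min(short, length(rest))))
    }
    sample(picked)  # shuffle row order
  })

  truth <- true[out_idx]
  label <- withr::with_seed(config$seed + 2L, {
    flip <- runif(length(truth)) < config$label_noise
    shift <- sample.int(K - 1L, length(truth), replace = TRUE)
    ifelse(flip, 1L + (truth - 1L + shift) %% K, truth)
  })

  out <- tibble(
    victim_id = drugs$drug_id[pool$a[out_idx]],
    perpetrator_id = drugs$drug_id[pool$b[out_idx]],
    label = as.integer(label)
  )
  attr(out, "true_label") <- as.integer(truth)
  attr(out, "bayes_accuracy") <-
    1 - config$label_noise * (K - 1) / K
  attr(out, "rule") <- list(mw_cuts = mw_cuts, chi1_cuts = rg_cuts)
  out
}
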