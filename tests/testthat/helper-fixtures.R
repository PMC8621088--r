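# Shared builders for the test suite; everything is generated in code.

# small drug table in normalized form, with fixed CYP roles
tiny_drug_table <- function() {
  drugs <- tibble::tibble(
    drug_id = c("d1", "d2", "d3", "d4"),
    smiles = c("CCO", "CC(=O)Nc1ccc(O)cc1", "c1ccncc1CC", "C1CCCCC1O")
  )
  for (e in cyp_enzymes()) {
    drugs[[paste0("sub_", e)]] <- 0L
    drugs[[paste0("perp_", e)]] <- "none"
  }
  drugs$sub_1A2 <- c(1L, 0L, 1L, 0L)
  drugs$sub_3A4 <- c(1L, 1L, 0L, 0L)
  drugs$perp_2B6 <- c("none", "inhibitor", "none", "none")
  drugs$perp_3A4 <- c("none", "inducer", "inhibitor", "none")
  drugs
}

tiny_pair_table <- function() {
  tibble::tibble(
    victim_id = c("d1", "d2", "d3", "d4", "d1"),
    perpetrator_id = c("d2", "d1", "d4", "d3", "d3"),
    label = c(1L, 2L, 1L, 3L, 2L)
  )
}

# brute-force double-loop oracles for the combination operators
oracle_cross <- function(fa, fb) {
  p <- length(fa)
  out <- numeric(p^2)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    out[(i - 1) * p + j] <- fa[i] * fb[j]
  }
  out
}

oracle_sum_product <- function(fa, fb) {
  p <- length(fa)
  out <- numeric(2 * p)
  for (i in seq_len(p)) {
    out[i] <- fa[i] + fb[i]
    out[p + i] <- fa[i] * fb[i]
  }
  out
}

# per-enzyme conditional oracle for the CYP interaction vector
oracle_cyp_interaction <- function(victim, perp) {
  out <- integer(12)
  for (e in 1:12) {
    out[e] <- if (victim[e] != 0 && perp[e] != 0) {
      victim[e] * sign(perp[e])
    } else 0L
  }
  out
}

# cheap content fingerprint used by no-leakage assertions
digest_rows <- function(df) {
  paste(format(as.matrix(df), digits = 15), collapse = "|")
}

# brute-force one-vs-rest recount of confusion entries
oracle_confusion <- function(y_true, y_pred, cl) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(y_true)) {
    t_pos <- y_true[i] == cl
    p_pos <- y_pred[i] == cl
    if (t_pos && p_pos) tp <- tp + 1L
    else if (!t_pos && p_pos) fp <- fp + 1L
    else if (t_pos && !p_pos) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}
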