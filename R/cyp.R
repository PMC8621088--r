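# CYP450 metabolism-profile encoding.
#
# A directional pair "A affected by B" is summarised at the enzyme level:
# the victim A contributes a 0/1 substrate vector, the perpetrator B a
# signed vector (+1 inhibits, -1 induces, 0 no interaction), and their
# elementwise product is the 12-component interaction vector.  A +1
# component means B blocks an enzyme that metabolises A (victim
# concentration rises); a -1 component means B accelerates it.

.cyp_panel <- c("1A2", "2A6", "2B6", "2C18", "2C19", "2C8", "2C9", "2D6",
                "2E1", "3A4", "3A5", "3A7")

#' The fixed CYP450 enzyme panel
#'
#' Twelve enzymes in an immutable order; every encoded vector follows this
#' order.
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' cyp_enzymes()
cyp_enzymes <- function() .cyp_panel

.check_enzymes <- function(x, what) {
  bad <- setdiff(x, .cyp_panel)
  if (length(bad)) {
    abort(paste0("unknown CYP enzyme(s) in ", what, ": ",
                 paste(bad, collapse = ", ")),
          class = "ddihybrid_schema_error")
  }
}

#' CYP metabolism profile of one drug
#'
#' @param drug_id Drug identifier.
#' @param substrates Enzymes (subset of [cyp_enzymes()]) that metabolise the
#'   drug.
#' @param inhibitors,inducers Enzymes the drug inhibits / induces.  A drug
#'   may be both substrate and perpetrator at the same enzyme, but cannot
#'   inhibit and induce the same enzyme.
#' @return A `cyp_profile` object.
#' @export
#' @examples
#' cyp_profile("d1", substrates = c("1A2", "3A4"), inhibitors = "2C9")
cyp_profile <- function(drug_id = NA_character_, substrates = character(),
                        inhibitors = character(), inducers = character()) {
  .check_enzymes(substrates, "substrates")
  .check_enzymes(inhibitors, "inhibitors")
  .check_enzymes(inducers, "inducers")
  structure(
    list(drug_id = drug_id, substrates = unique(substrates),
         inhibitors = unique(inhibitors), inducers = unique(inducers)),
    class = "cyp_profile"
  )
}

#' @export
print.cyp_profile <- function(x, ...) {
  cat("<cyp_profile ", x$drug_id, ": substrate of {",
      paste(x$substrates, collapse = ","), "}, inhibits {",
      paste(x$inhibitors, collapse = ","), "}, induces {",
      paste(x$inducers, collapse = ","), "}>\n", sep = "")
  invisible(x)
}

#' Encode the victim-side substrate vector
#'
#' Component `e` is 1 if the victim drug is a substrate of enzyme `e`,
#' otherwise 0, in panel order.
#'
#' @param profile A [cyp_profile()], or a character vector of substrate
#'   enzymes.
#' @return Named integer vector of length 12 with values in \{0, 1\}.
#' @export
#' @examples
#' encode_victim(c("1A2", "3A4"))
encode_victim <- function(profile) {
  subs <- if (inherits(profile, "cyp_profile")) profile$substrates else profile
  .check_enzymes(subs, "substrates")
  setNames(as.integer(.cyp_panel %in% subs), .cyp_panel)
}

#' Encode the perpetrator-side vector
#'
#' Component `e` is +1 if the perpetrator inhibits enzyme `e`, -1 if it
#' induces it, 0 otherwise.  A drug listed as both inhibitor and inducer of
#' the same enzyme is a conflict: the default policy raises an error; the
#' alternatives resolve it deterministically.
#'
#' @param profile A [cyp_profile()]; alternatively pass `inhibitors` /
#'   `inducers` directly.
#' @param inhibitors,inducers Character vectors of enzymes (used when
#'   `profile` is missing).
#' @param conflict One of `"error"`, `"prefer-inhibitor"`,
#'   `"prefer-inducer"`, `"zero"`.
#' @return Named integer vector of length 12 with values in \{-1, 0, 1\}.
#' @export
#' @examples
#' encode_perpetrator(inhibitors = c("2B6", "2C8"), inducers = c("2D6", "3A4"))
encode_perpetrator <- function(profile = NULL, inhibitors = character(),
                               inducers = character(),
                               conflict = c("error", "prefer-inhibitor",
                                            "prefer-inducer", "zero")) {
  conflict <- match.arg(conflict)
  if (inherits(profile, "cyp_profile")) {
    inhibitors <- profile$inhibitors
    inducers <- profile$inducers
  } else if (!is.null(profile)) {
    abort("profile must be a cyp_profile (or NULL with inhibitors/inducers)",
          class = "ddihybrid_schema_error")
  }
  .check_enzymes(inhibitors, "inhibitors")
  .check_enzymes(inducers, "inducers")
  both <- intersect(inhibitors, inducers)
  if (length(both)) {
    if (conflict == "error") {
      abort(paste0("enzyme(s) listed as both inhibited and induced: ",
                   paste(both, collapse = ", ")),
            class = "ddihybrid_conflict_error")
    }
    if (conflict == "prefer-inhibitor") inducers <- setdiff(inducers, both)
    if (conflict == "prefer-inducer") inhibitors <- setdiff(inhibitors, both)
    if (conflict == "zero") {
      inhibitors <- setdiff(inhibitors, both)
      inducers <- setdiff(inducers, both)
    }
  }
  out <- as.integer(.cyp_panel %in% inhibitors) -
    as.integer(.cyp_panel %in% inducers)
  setNames(out, .cyp_panel)
}

#' CYP interaction vector of an ordered pair
#'
#' Elementwise product of the victim and perpetrator vectors: nonzero only
#' at enzymes that both metabolise the victim and are perturbed by the
#' perpetrator.
#'
#' @param victim Length-12 integer vector from [encode_victim()].
#' @param perpetrator Length-12 integer vector from [encode_perpetrator()].
#' @return Named integer vector of length 12 with values in \{-1, 0, 1\}.
#' @export
#' @examples
#' v <- encode_victim(c("1A2", "3A4"))
#' p <- encode_perpetrator(inhibitors = c("2B6", "2C8"),
#'                         inducers = c("2D6", "3A4"))
#' cyp_interaction(v, p)
cyp_interaction <- function(victim, perpetrator) {
  if (length(victim) != 12L || length(perpetrator) != 12L) {
    abort("victim and perpetrator vectors must have length 12",
          class = "ddihybrid_dimension_error")
  }
  setNames(as.integer(victim) * as.integer(perpetrator), .cyp_panel)
}

#' CYP interaction features for a pair table
#'
#' Encodes every drug's profile from the (normalized) drug table and forms
#' the 12 interaction components for each ordered pair; these are the
#' CYP-side columns of the hybrid feature row.
#'
#' @param pairs Data frame with `victim_id` and `perpetrator_id`.
#' @param drugs Drug table as returned by [read_drug_table()] /
#'   [generate_drug_library()] (columns `sub_<enzyme>` and `perp_<enzyme>`).
#' @return A tibble: `victim_id`, `perpetrator_id`, then `CYP_<enzyme>`
#'   columns in panel order.
#' @export
cyp_interaction_features <- function(pairs, drugs) {
  stopifnot(all(c("victim_id", "perpetrator_id") %in% names(pairs)))
  enc <- encode_cyp_vectors(drugs)
  missing_ids <- setdiff(unique(c(pairs$victim_id, pairs$perpetrator_id)),
                         enc$drug_id)
  if (length(missing_ids)) {
    abort(paste0("pairs reference drugs absent from the drug table: ",
                 paste(head(missing_ids, 5), collapse = ", ")),
          class = "ddihybrid_schema_error")
  }
  vm <- as.matrix(enc[, paste0("victim_", .cyp_panel)])
  pm <- as.matrix(enc[, paste0("perp_", .cyp_panel)])
  rownames(vm) <- rownames(pm) <- enc$drug_id
  out <- vm[pairs$victim_id, , drop = FALSE] *
    pm[pairs$perpetrator_id, , drop = FALSE]
  colnames(out) <- paste0("CYP_", .cyp_panel)
  bind_cols(
    tibble(victim_id = pairs$victim_id, perpetrator_id = pairs$perpetrator_id),
    as_tibble(out)
  )
}

#' Victim and perpetrator vectors for a whole drug table
#'
#' @param drugs Normalized drug table with `sub_<enzyme>` (0/1) and
#'   `perp_<enzyme>` ("none"/"inhibitor"/"inducer") columns.
#' @return A tibble with `drug_id`, `victim_<enzyme>` and `perp_<enzyme>`
#'   integer columns.
#' @export
encode_cyp_vectors <- function(drugs) {
  sub_cols <- paste0("sub_", .cyp_panel)
  perp_cols <- paste0("perp_", .cyp_panel)
  missing <- setdiff(c(sub_cols, perp_cols), names(drugs))
  if (length(missing)) {
    abort(paste0("drug table lacks CYP column(s): ",
                 paste(head(missing, 5), collapse = ", "),
                 "; read it with read_drug_table()"),
          class = "ddihybrid_schema_error")
  }
  vm <- vapply(sub_cols, function(cl) as.integer(drugs[[cl]] != 0),
               integer(nrow(drugs)))
  pm <- vapply(perp_cols, function(cl) {
    x <- as.character(drugs[[cl]])
    bad <- setdiff(unique(x), c("none", "inhibitor", "inducer"))
    if (length(bad)) {
      abort(paste0("bad perpetrator role token(s) in ", cl, ": ",
                   paste(bad, collapse = ", ")),
            class = "ddihybrid_schema_error")
    }
    ifelse(x == "inhibitor", 1L, ifelse(x == "inducer", -1L, 0L))
  }, integer(nrow(drugs)))
  vm <- matrix(vm, nrow = nrow(drugs),
               dimnames = list(NULL, paste0("victim_", .cyp_panel)))
  pm <- matrix(pm, nrow = nrow(drugs),
               dimnames = list(NULL, paste0("perp_", .cyp_panel)))
  bind_cols(tibble(drug_id = drugs$drug_id), as_tibble(vm), as_tibble(pm))
}
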