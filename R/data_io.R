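# Flat data model: drug table, directional pair table, label catalog.
#
# drugs:  drug_id, smiles, plus one CYP column block in either dialect:
#           single-column:  cyp_<enzyme> in {substrate, inhibitor, inducer, none}
#           two-column:     cyp_substrate_<enzyme> in {substrate, none}
#                           cyp_perpetrator_<enzyme> in {inhibitor, inducer, none}
#         The two-column dialect is the writer default because a drug can be
#         both substrate and perpetrator at one enzyme.
# pairs:  victim_id, perpetrator_id, label (integer class)
# labels: label, description (templates with DRUG_A / DRUG_B placeholders)

.detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

.read_delim_quiet <- function(path, delim) {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

#' Read and validate a drug table
#'
#' Accepts comma- or tab-delimited text (auto-detected) in either CYP
#' dialect and returns the normalized form used throughout the package:
#' `drug_id`, `smiles`, `sub_<enzyme>` (0/1) and `perp_<enzyme>`
#' (`"none"`/`"inhibitor"`/`"inducer"`).
#'
#' @param path Path to the delimited file (UTF-8, header row).
#' @param delim Field delimiter; `NULL` auto-detects comma vs tab.
#' @return Normalized drug tibble.
#' @export
read_drug_table <- function(path, delim = NULL) {
  raw <- .read_delim_quiet(path, delim %||% .detect_delim(path))
  need <- c("drug_id", "smiles")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(paste0("drug table missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "ddihybrid_schema_error")
  }
  dup <- raw$drug_id[duplicated(raw$drug_id)]
  if (length(dup)) {
    abort(paste0("duplicated drug_id: ", paste(unique(dup), collapse = ", ")),
          class = "ddihybrid_schema_error")
  }
  if (any(is.na(raw$smiles) | !nzchar(raw$smiles))) {
    abort("empty smiles entries in drug table",
          class = "ddihybrid_schema_error")
  }
  single <- paste0("cyp_", .cyp_panel)
  twosub <- paste0("cyp_substrate_", .cyp_panel)
  twoperp <- paste0("cyp_perpetrator_", .cyp_panel)
  out <- tibble(drug_id = as.character(raw$drug_id), smiles = raw$smiles)
  if (all(single %in% names(raw))) {
    for (k in seq_along(.cyp_panel)) {
      tok <- as.character(raw[[single[k]]])
      .check_role_tokens(tok, single[k],
                         c("substrate", "inhibitor", "inducer", "none"))
      out[[paste0("sub_", .cyp_panel[k])]] <- as.integer(tok == "substrate")
      out[[paste0("perp_", .cyp_panel[k])]] <-
        ifelse(tok %in% c("inhibitor", "inducer"), tok, "none")
    }
  } else if (all(c(twosub, twoperp) %in% names(raw))) {
    for (k in seq_along(.cyp_panel)) {
      s <- as.character(raw[[twosub[k]]])
      p <- as.character(raw[[twoperp[k]]])
      .check_role_tokens(s, twosub[k], c("substrate", "none"))
      .check_role_tokens(p, twoperp[k], c("inhibitor", "inducer", "none"))
      out[[paste0("sub_", .cyp_panel[k])]] <- as.integer(s == "substrate")
      out[[paste0("perp_", .cyp_panel[k])]] <- p
    }
  } else {
    abort(paste0("drug table has neither the single-column (cyp_<enzyme>) ",
                 "nor the two-column (cyp_substrate_/cyp_perpetrator_) ",
                 "CYP dialect"),
          class = "ddihybrid_schema_error")
  }
  out
}

.check_role_tokens <- function(tok, column, allowed) {
  bad <- which(!tok %in% allowed)
  if (length(bad)) {
    abort(sprintf("bad CYP role token '%s' in column %s, row %d",
                  tok[bad[1]], column, bad[1]),
          class = "ddihybrid_schema_error")
  }
}

#' Write a drug table
#'
#' Emits the two-column CYP dialect (the writer default, since it can
#' represent drugs that are both substrate and perpetrator at one enzyme).
#'
#' @param drugs Normalized drug tibble (see [read_drug_table()]).
#' @param path Output path.
#' @param delim Field delimiter (`","` or `"\t"`).
#' @return `path`, invisibly.
#' @export
write_drug_table <- function(drugs, path, delim = ",") {
  out <- tibble(drug_id = drugs$drug_id, smiles = drugs$smiles)
  for (e in .cyp_panel) {
    out[[paste0("cyp_substrate_", e)]] <-
      ifelse(drugs[[paste0("sub_", e)]] != 0, "substrate", "none")
    out[[paste0("cyp_perpetrator_", e)]] <- drugs[[paste0("perp_", e)]]
  }
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Read and validate a directional pair table
#'
#' @param path Path to delimited text with columns `victim_id`,
#'   `perpetrator_id`, `label`.
#' @param drugs Optional drug table; if given, every id must be present and
#'   self-pairs are rejected.
#' @param catalog Label catalog tibble; labels outside it are rejected.
#' @param delim Field delimiter; `NULL` auto-detects.
#' @return Tibble `victim_id`, `perpetrator_id`, `label` (integer).  Exact
#'   duplicate rows are dropped with a warning; the two directions of a pair
#'   are distinct records.
#' @export
read_ddi_table <- function(path, drugs = NULL, catalog = label_catalog(),
                           delim = NULL) {
  raw <- .read_delim_quiet(path, delim %||% .detect_delim(path))
  need <- c("victim_id", "perpetrator_id", "label")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(paste0("pair table missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "ddihybrid_schema_error")
  }
  out <- tibble(victim_id = as.character(raw$victim_id),
                perpetrator_id = as.character(raw$perpetrator_id),
                label = as.integer(raw$label))
  if (any(duplicated(out))) {
    warn(paste0("dropped ", sum(duplicated(out)), " exact duplicate pair row(s)"))
    out <- out[!duplicated(out), ]
  }
  if (any(out$victim_id == out$perpetrator_id)) {
    abort("self-pairs (victim_id == perpetrator_id) are not allowed",
          class = "ddihybrid_schema_error")
  }
  bad_lab <- setdiff(out$label, catalog$label)
  if (length(bad_lab)) {
    abort(paste0("labels outside the catalog: ",
                 paste(bad_lab, collapse = ", ")),
          class = "ddihybrid_schema_error")
  }
  if (!is.null(drugs)) {
    missing_ids <- setdiff(unique(c(out$victim_id, out$perpetrator_id)),
                           drugs$drug_id)
    if (length(missing_ids)) {
      abort(paste0("pair table references unknown drug id(s): ",
                   paste(head(missing_ids, 5), collapse = ", ")),
            class = "ddihybrid_schema_error")
    }
  }
  out
}

#' Write a directional pair table
#'
#' @param pairs Tibble with `victim_id`, `perpetrator_id`, `label`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_ddi_table <- function(pairs, path, delim = ",") {
  readr::write_delim(
    pairs[, c("victim_id", "perpetrator_id", "label")], path, delim = delim
  )
  invisible(path)
}

#' The 19-class interaction label catalog
#'
#' Each class maps to a description template with `DRUG_A` (victim) and
#' `DRUG_B` (perpetrator) placeholders.  Classes 1-7 describe interactions
#' without a CYP-mediated mechanism, 8-13 increased victim exposure through
#' inhibition of a metabolising enzyme group, and 14-19 decreased exposure
#' through induction.
#'
#' @return Tibble with columns `label` (1..19) and `description`.
#' @export
#' @examples
#' label_catalog()
label_catalog <- function() {
  groups <- c("1A2/2A6", "2B6/2C18", "2C19/2C8", "2C9/2D6", "2E1/3A4",
              "3A5/3A7")
  tibble(
    label = 1:19,
    description = c(
      paste0("DRUG_B can alter the activity or exposure of DRUG_A through ",
             "a non-CYP mechanism (category ", 1:7, ")."),
      paste0("The serum concentration of DRUG_A can be increased when ",
             "combined with DRUG_B (inhibition of CYP", groups, ")."),
      paste0("The serum concentration of DRUG_A can be decreased when ",
             "combined with DRUG_B (induction of CYP", groups, ").")
    )
  )
}

#' Write the label catalog
#'
#' @param catalog Output of [label_catalog()] (or a custom one with the same
#'   columns).
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_label_catalog <- function(catalog = label_catalog(), path,
                                delim = ",") {
  readr::write_delim(catalog, path, delim = delim)
  invisible(path)
}

#' Drop classes below a frequency cutoff
#'
#' Removes records whose class has fewer than `min_count` members; the
#' surviving class ids keep their original values (no relabeling).  Long
#' tails of rare interaction types otherwise leave classes too small to
#' split or cross-validate.
#'
#' @param pairs Tibble with a `label` column.
#' @param min_count Minimum class frequency to keep (default 50).
#' @return Filtered tibble; removed classes are reported in a message.
#' @export
filter_low_count_classes <- function(pairs, min_count = 50) {
  stopifnot(min_count >= 1)
  counts <- table(pairs$label)
  keep <- as.integer(names(counts)[counts >= min_count])
  dropped <- setdiff(as.integer(names(counts)), keep)
  if (length(dropped)) {
    message("filter_low_count_classes: removed class(es) ",
            paste(dropped, collapse = ", "), " (< ", min_count, " records)")
  }
  pairs[pairs$label %in% keep, , drop = FALSE]
}

#' Stratified train/test split
#'
#' Partitions records into train and test sets preserving per-class
#' proportions (per-class rounding of `train_fraction`), deterministically
#' for a given seed.
#'
#' @param pairs Tibble with a `label` column.
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.70).
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test`; together they partition the
#'   input.
#' @export
stratified_split <- function(pairs, train_fraction = 0.70, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  counts <- table(pairs$label)
  singletons <- names(counts)[counts < 2]
  if (length(singletons)) {
    abort(paste0("class(es) with a single record cannot be split: ",
                 paste(singletons, collapse = ", "),
                 "; apply filter_low_count_classes() first"),
          class = "ddihybrid_error")
  }
  idx_train <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(pairs)), pairs$label), function(ix) {
      n_tr <- round(train_fraction * length(ix))
      n_tr <- min(max(n_tr, 1L), length(ix) - 1L)  # both sides non-empty
      sample(ix, n_tr)
    }), use.names = FALSE)
  })
  list(train = pairs[sort(idx_train), , drop = FALSE],
       test = pairs[setdiff(seq_len(nrow(pairs)), idx_train), , drop = FALSE])
}
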