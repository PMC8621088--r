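# Molecular descriptor provider.
#
# Descriptors are computed on the heavy-atom graph parsed from SMILES via
# ChemmineR/OpenBabel.  The default set is a fixed, ordered 60-descriptor
# panel: 24 constitutional counts, 18 topological indices, and 18 MOE-type
# VSA bins (molar-refractivity and logP partitioned surface areas).  All
# descriptors are graph invariants, so any SMILES respelling of the same
# molecule yields the same vector.

# element lookup tables; implicit hydrogens filled from the lowest standard
# valence accommodating the kekulized bond-order sum
.elem <- local({
  tab <- tibble::tribble(
    ~symbol, ~mass,   ~zv, ~valences,   ~r_vdw, ~r_cov, ~mr_aliph, ~mr_arom, ~logp_aliph, ~logp_arom,
    "C",     12.011,  4,   list(4),      1.70,  0.77,   2.50,      3.50,     0.14,        0.29,
    "N",     14.007,  5,   list(3),      1.55,  0.75,   2.70,      3.00,    -0.60,       -0.26,
    "O",     15.999,  6,   list(2),      1.52,  0.73,   1.80,      1.80,    -0.40,       -0.40,
    "S",     32.06,   6,   list(c(2, 4, 6)), 1.80, 1.02, 7.30,     7.00,     0.65,        0.65,
    "P",     30.974,  5,   list(c(3, 5)), 1.80, 1.06,   6.92,      6.92,     0.86,        0.86,
    "F",     18.998,  7,   list(1),      1.47,  0.71,   1.06,      1.06,     0.44,        0.44,
    "Cl",    35.45,   7,   list(1),      1.75,  0.99,   5.85,      5.85,     0.64,        0.64,
    "Br",    79.904,  7,   list(1),      1.85,  1.14,   8.74,      8.74,     0.89,        0.89,
    "I",     126.904, 7,   list(1),      1.98,  1.33,  13.90,     13.90,     0.51,        0.51,
    "B",     10.81,   3,   list(3),      1.92,  0.85,   3.60,      3.60,    -0.18,       -0.18,
    "Si",    28.085,  4,   list(4),      2.10,  1.11,   7.90,      7.90,     0.08,        0.08
  )
  rownames_tab <- as.data.frame(tab)
  rownames(rownames_tab) <- tab$symbol
  rownames_tab
})

.h_mass <- 1.008
.h_r_vdw <- 1.20
.h_r_cov <- 0.37
.mr_h <- 1.03
.logp_h_on_c <- 0.12
.logp_h_on_het <- -0.20

# bin upper edges; value falls in bin b when edge[b-1] < x <= edge[b]
.mrvsa_edges <- c(2.0, 2.6, 3.2, 3.8, 4.5, 5.0, 5.65, 6.5, Inf)
.logpvsa_edges <- c(-0.45, -0.30, -0.15, 0.00, 0.15, 0.30, 0.45, 0.60, Inf)

.descriptor_names_60 <- c(
  "MW", "nAtom", "nBond", "nC", "nN", "nO", "nS", "nP", "nF", "nCl", "nBr",
  "nI", "nHal", "nHet", "nH", "nSingle", "nDouble", "nTriple", "nRing",
  "nAromRing", "nAromAtom", "nRotB", "nHBD", "nHBA",
  "Wiener", "Zagreb1", "Zagreb2", "Chi0", "Chi1", "Chi0v", "Chi1v",
  "BalabanJ", "Platt", "Radius", "Diameter", "MeanDist", "EccConn",
  "nTerminalAtom", "MaxDegree", "MeanDegree", "Kappa1", "Kappa2",
  paste0("MRVSA", 1:9), paste0("LogPVSA", 1:9)
)

#' Descriptor set provider
#'
#' Returns the named, ordered descriptor set used to turn a molecule into a
#' fixed-length numeric vector.  The default `"hybrid60"` set has exactly 60
#' descriptors, so the pairwise cross-product operator yields 3600 features
#' and the concatenation / sum-product operators yield 120 each.  Alternative
#' backends can be plugged in by constructing a set with the same structure
#' (`name`, ordered `names`, and a `compute(mol)` function).
#'
#' @param name Name of the descriptor set. Only `"hybrid60"` ships with the
#'   package.
#' @return An object of class `descriptor_set`: a list with elements `name`,
#'   `names` (ordered descriptor names) and `compute` (function taking a
#'   parsed molecule and returning a numeric vector).
#' @export
#' @examples
#' ds <- descriptor_set()
#' length(ds$names)
descriptor_set <- function(name = "hybrid60") {
  if (!identical(name, "hybrid60")) {
    abort(paste0("unknown descriptor set '", name, "'"),
          class = "ddihybrid_error")
  }
  structure(
    list(name = "hybrid60", names = .descriptor_names_60,
         compute = .compute_hybrid60),
    class = "descriptor_set"
  )
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat("<descriptor_set '", x$name, "': ", length(x$names), " descriptors>\n",
      sep = "")
  invisible(x)
}

#' Canonicalize SMILES strings
#'
#' Validates and canonicalizes SMILES through OpenBabel.  Unparseable strings
#' raise an error of class `ddihybrid_parse_error` carrying the offending
#' input.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length and order.
#' @export
#' @examples
#' canonicalize_smiles(c("CCO", "OCC"))
canonicalize_smiles <- function(smiles) {
  .assert_parseable(smiles)
  input <- paste0(smiles, "\tm", seq_along(smiles), "\n", collapse = "")
  out <- ChemmineOB::convertFormat("SMI", "CAN", input)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

# Raise ddihybrid_parse_error unless every SMILES string passes lexical
# validation.  OpenBabel silently repairs malformed strings (e.g. "C((" is
# read as methane), so syntactic validity has to be established before
# handing the string to the converter.
.assert_parseable <- function(smiles) {
  if (!is.character(smiles) || any(is.na(smiles)) || any(!nzchar(smiles))) {
    abort("smiles must be a character vector of non-empty strings",
          class = "ddihybrid_parse_error")
  }
  bad <- smiles[!vapply(smiles, .smiles_syntax_ok, logical(1))]
  if (length(bad)) {
    abort(
      paste0("unparseable SMILES: ", paste(unique(bad), collapse = ", ")),
      class = "ddihybrid_parse_error", smiles = unique(bad)
    )
  }
  invisible(smiles)
}

# Lexical SMILES check: legal tokens only, balanced parentheses, no empty
# branches, paired ring-closure labels, and no trailing bond.  This is a
# validator, not a parser; structural interpretation stays with OpenBabel.
.smiles_syntax_ok <- function(s) {
  tok_re <- paste0(
    "\\[[^\\[\\]]+\\]|Cl|Br|Si|[BCNOPSFI]|[bcnops]|",
    "%[0-9]{2}|[0-9]|[-=#$:/\\\\.~]|[()]"
  )
  toks <- regmatches(s, gregexpr(tok_re, s))[[1]]
  if (sum(nchar(toks)) != nchar(s)) return(FALSE)  # illegal characters
  depth <- 0L
  prev <- ""
  rings <- integer()
  for (t in toks) {
    if (t == "(") {
      if (prev %in% c("", "(", ".")) return(FALSE)
      depth <- depth + 1L
    } else if (t == ")") {
      if (depth == 0L || prev %in% c("(", "", ".")) return(FALSE)
      depth <- depth - 1L
    } else if (grepl("^%?[0-9]+$", t)) {
      if (prev %in% c("", "(", ".")) return(FALSE)
      lab <- sub("^%", "", t)
      rings[lab] <- (rings[lab] %||% 0L) + 1L
      if (is.na(rings[lab])) rings[lab] <- 1L
    }
    prev <- t
  }
  if (depth != 0L) return(FALSE)
  if (grepl("[-=#$:/\\\\.~]$|^[-=#$:/\\\\.~]", s)) return(FALSE)
  all(rings %% 2L == 0L)
}

# Parse SMILES into light molecule structures: element vector, formal
# charges, implicit hydrogen counts, aromatic flags and a bond table.
# Inputs are assumed canonical (see compute_descriptors); ChemmineR loses
# the atom identity of single-atom molecules, so those are reconstructed
# from the canonical SMILES token directly.
.parse_molecules <- function(smiles) {
  .assert_parseable(smiles)
  sdf <- suppressWarnings(
    ChemmineR::smiles2sdf(setNames(smiles, paste0("m", seq_along(smiles))))
  )
  lapply(seq_along(smiles), function(i) .mol_from_sdf(sdf[[i]], smiles[i]))
}

.old_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

.mol_from_sdf <- function(sdfobj, smi) {
  counts <- ChemmineR::header(sdfobj)[["Counts_Line"]]
  n_decl <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  if (!is.na(n_decl) && n_decl == 1L) return(.mol_single_atom(smi))
  ab <- ChemmineR::atomblock(sdfobj)
  elements <- gsub("_.*$", "", rownames(ab))
  n <- length(elements)
  charge <- rep(0L, n)
  if ("C6" %in% colnames(ab)) {  # V2000 old-style charge field
    raw <- as.integer(ab[, "C6"])
    raw[is.na(raw) | raw < 0 | raw > 7] <- 0L
    charge <- unname(.old_charge[as.character(raw)])
  }
  bb <- ChemmineR::bondblock(sdfobj)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = length(bb) > 0)
  if (NROW(bb) > 0) {
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }

  arom <- rep(FALSE, n)
  n_arom_ring <- 0L
  if (nrow(bonds) >= n) {  # only cyclic graphs can hold aromatic rings
    rr <- tryCatch(
      ChemmineR::rings(sdfobj, type = "arom", arom = TRUE),
      error = function(e) NULL
    )
    if (!is.null(rr) && length(rr$AROMATIC_RINGS)) {
      n_arom_ring <- length(rr$AROMATIC_RINGS)
      idx <- unique(unlist(lapply(rr$AROMATIC_RINGS, function(r) {
        as.integer(gsub("^.*_", "", r))
      })))
      arom[idx] <- TRUE
    }
  }

  # bond-order sum per atom (kekulized orders)
  bsum <- rep(0L, n)
  if (nrow(bonds)) {
    agg <- tapply(c(bonds$order, bonds$order), c(bonds$i, bonds$j), sum)
    bsum[as.integer(names(agg))] <- as.integer(agg)
  }
  nh <- vapply(seq_len(n), function(a) {
    el <- elements[a]
    if (!el %in% rownames(.elem)) return(0L)
    vals <- unlist(.elem[el, "valences"])
    need <- bsum[a] + abs(charge[a]) * 0L  # charge handled by clamping below
    v <- vals[vals >= need]
    v <- if (length(v)) min(v) else max(vals)
    as.integer(max(0L, v - bsum[a] + charge[a] * ifelse(el %in% c("N", "O"), 1L, 0L)))
  }, integer(1))

  list(elements = elements, charge = charge, nh = nh, arom = arom,
       bonds = bonds, n = n, n_arom_ring = n_arom_ring)
}

# single heavy atom, e.g. "C", "O", "[NH4+]": element, charge and explicit H
# read off the (canonical) SMILES token
.mol_single_atom <- function(smi) {
  body <- sub("^\\[", "", sub("\\]$", "", smi))
  elm <- regmatches(body, regexpr("^[A-Z][a-z]?|^[bcnops]", body))
  element <- if (length(elm)) {
    paste0(toupper(substr(elm, 1, 1)), substr(elm, 2, 2))
  } else "C"
  charge <- 0L
  if (grepl("\\+", smi)) {
    charge <- max(1L, suppressWarnings(
      as.integer(sub(".*\\+([0-9]+).*", "\\1", smi))), na.rm = TRUE)
  } else if (grepl("-", smi)) {
    charge <- -max(1L, suppressWarnings(
      as.integer(sub(".*-([0-9]+).*", "\\1", smi))), na.rm = TRUE)
  }
  nh <- if (grepl("H[0-9]", body)) {
    as.integer(sub(".*H([0-9]).*", "\\1", body))
  } else if (grepl("H", body)) 1L else if (!grepl("^\\[", smi)) {
    if (element %in% rownames(.elem)) {
      max(0L, as.integer(min(unlist(.elem[element, "valences"])) + charge))
    } else 0L
  } else 0L
  list(elements = element, charge = charge, nh = nh, arom = FALSE,
       bonds = data.frame(i = integer(), j = integer(), order = integer()),
       n = 1L, n_arom_ring = 0L)
}

# --- the hybrid60 computation ------------------------------------------------

.compute_hybrid60 <- function(mol) {
  el <- mol$elements
  n <- mol$n
  bonds <- mol$bonds
  m <- nrow(bonds)
  known <- el %in% rownames(.elem)

  cnt <- function(sym) sum(el == sym)
  n_hal <- cnt("F") + cnt("Cl") + cnt("Br") + cnt("I")
  n_het <- sum(known & el != "C")
  nh_tot <- sum(mol$nh)
  mw <- sum(.elem[el[known], "mass"]) + nh_tot * .h_mass

  deg <- rep(0L, n)
  if (m) {
    t1 <- table(factor(bonds$i, levels = seq_len(n)))
    t2 <- table(factor(bonds$j, levels = seq_len(n)))
    deg <- as.integer(t1 + t2)
  }

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (m) g <- igraph::add_edges(g, rbind(bonds$i, bonds$j))

  in_ring_edge <- rep(FALSE, m)
  if (m) {
    br <- igraph::bridges(g)
    in_ring_edge <- !(seq_len(m) %in% as.integer(br))
  }
  n_ring <- m - n + igraph::components(g)$no

  rotb <- if (m) sum(bonds$order == 1 & !in_ring_edge &
                       deg[bonds$i] >= 2 & deg[bonds$j] >= 2) else 0L
  hbd <- sum(el %in% c("N", "O") & mol$nh >= 1)
  hba <- sum(el %in% c("N", "O"))

  # topological block
  D <- igraph::distances(g)
  fin <- is.finite(D) & upper.tri(D)
  wiener <- sum(D[fin])
  zag1 <- sum(deg^2)
  zag2 <- if (m) sum(deg[bonds$i] * deg[bonds$j]) else 0
  platt <- if (m) sum(deg[bonds$i] + deg[bonds$j] - 2L) else 0
  chi0 <- sum(1 / sqrt(deg[deg > 0]))
  chi1 <- if (m) sum(1 / sqrt(deg[bonds$i] * deg[bonds$j])) else 0
  dv <- ifelse(known, .elem[el, "zv"] - mol$nh, 0)
  dv[dv < 0] <- 0
  chi0v <- sum(1 / sqrt(dv[dv > 0]))
  chi1v <- if (m) {
    dvi <- dv[bonds$i]; dvj <- dv[bonds$j]
    keep <- dvi > 0 & dvj > 0
    sum(1 / sqrt(dvi[keep] * dvj[keep]))
  } else 0

  balaban <- 0
  if (m > 0 && igraph::components(g)$no == 1 && n > 1) {
    s <- rowSums(D)
    gamma <- m - n + 1
    balaban <- m / (gamma + 1) * sum(1 / sqrt(s[bonds$i] * s[bonds$j]))
  }

  ecc <- vapply(seq_len(n), function(a) {
    d <- D[a, ]
    d <- d[is.finite(d)]
    if (length(d)) max(d) else 0
  }, numeric(1))
  radius <- if (n) min(ecc) else 0
  diam <- if (n) max(ecc) else 0
  mean_dist <- if (any(fin)) mean(D[fin]) else 0
  ecc_conn <- sum(deg * ecc)
  n_term <- sum(deg == 1)
  max_deg <- if (n) max(deg) else 0
  mean_deg <- if (n) mean(deg) else 0
  kappa1 <- if (m > 0) n * (n - 1)^2 / m^2 else 0
  p2 <- sum(choose(deg, 2))
  kappa2 <- if (p2 > 0) (n - 1) * (n - 2)^2 / p2^2 else 0

  # MOE-type VSA bins: per-atom approximate accessible surface area weighted
  # into bins of per-atom molar refractivity / logP contributions
  vsa <- .atom_vsa(mol)
  mr <- ifelse(mol$arom, .elem[el, "mr_arom"], .elem[el, "mr_aliph"])
  mr[!known] <- 0
  mr <- mr + mol$nh * .mr_h
  lp <- ifelse(mol$arom, .elem[el, "logp_arom"], .elem[el, "logp_aliph"])
  lp[!known] <- 0
  lp <- lp + mol$nh * ifelse(el == "C", .logp_h_on_c, .logp_h_on_het)

  bin_sum <- function(x, edges) {
    b <- vapply(x, function(v) which(v <= edges)[1], integer(1))
    vapply(seq_along(edges), function(k) sum(vsa[b == k]), numeric(1))
  }
  mrvsa <- bin_sum(mr, .mrvsa_edges)
  lpvsa <- bin_sum(lp, .logpvsa_edges)

  out <- c(
    mw, n, m, cnt("C"), cnt("N"), cnt("O"), cnt("S"), cnt("P"), cnt("F"),
    cnt("Cl"), cnt("Br"), cnt("I"), n_hal, n_het, nh_tot,
    if (m) sum(bonds$order == 1) else 0, if (m) sum(bonds$order == 2) else 0,
    if (m) sum(bonds$order == 3) else 0, n_ring,
    mol$n_arom_ring, sum(mol$arom),
    rotb, hbd, hba,
    wiener, zag1, zag2, chi0, chi1, chi0v, chi1v, balaban, platt,
    radius, diam, mean_dist, ecc_conn, n_term, max_deg, mean_deg,
    kappa1, kappa2,
    mrvsa, lpvsa
  )
  names(out) <- .descriptor_names_60
  out
}

# Labute-style approximate van der Waals surface area per heavy atom:
# sphere area minus spherical caps hidden by bonded neighbours (implicit
# hydrogens included as neighbours), clamped at zero.
.atom_vsa <- function(mol) {
  el <- mol$elements
  known <- el %in% rownames(.elem)
  ri <- ifelse(known, .elem[el, "r_vdw"], 1.7)
  rci <- ifelse(known, .elem[el, "r_cov"], 0.77)
  area <- 4 * pi * ri^2
  cap <- function(r1, r2, d) {
    d <- pmin(pmax(d, abs(r1 - r2) + 1e-6), r1 + r2 - 1e-6)
    h <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
    pmax(0, 2 * pi * r1 * h)
  }
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[b]; j <- mol$bonds$j[b]; o <- mol$bonds$order[b]
      d <- rci[i] + rci[j] - 0.12 * (o - 1)
      area[i] <- area[i] - cap(ri[i], ri[j], d)
      area[j] <- area[j] - cap(ri[j], ri[i], d)
    }
  }
  nh <- mol$nh
  hcap <- cap(ri, rep(.h_r_vdw, mol$n), rci + .h_r_cov)
  area <- area - nh * hcap
  pmax(area, 0)
}

#' Compute molecular descriptor vectors from SMILES
#'
#' Parses each SMILES string, canonicalizes it, and computes the fixed,
#' ordered descriptor panel.  The descriptor order is identical for every
#' drug in a run, and values are invariant under SMILES respellings of the
#' same molecule.  Non-finite descriptor values (which can arise for exotic
#' valence states) are imputed to 0 with a warning.
#'
#' @param drugs A data frame with columns `drug_id` and `smiles`, or a bare
#'   character vector of SMILES strings (names become drug ids).
#' @param set A [descriptor_set()].
#' @return A tibble with one row per drug: `drug_id` followed by one column
#'   per descriptor, in the set's declared order.
#' @export
#' @examples
#' compute_descriptors(tibble::tibble(drug_id = "d1", smiles = "CCO"))
compute_descriptors <- function(drugs, set = descriptor_set()) {
  if (is.character(drugs)) {
    ids <- names(drugs) %||% paste0("drug", seq_along(drugs))
    drugs <- tibble(drug_id = ids, smiles = unname(drugs))
  }
  stopifnot(all(c("drug_id", "smiles") %in% names(drugs)))
  canon <- canonicalize_smiles(drugs$smiles)
  uniq <- unique(canon)
  mols <- .parse_molecules(uniq)
  vals <- vapply(mols, set$compute, numeric(length(set$names)))
  vals <- t(vals)
  if (any(!is.finite(vals))) {
    warn(paste0("imputed ", sum(!is.finite(vals)),
                " non-finite descriptor value(s) to 0"))
    vals[!is.finite(vals)] <- 0
  }
  rownames(vals) <- uniq
  out <- as_tibble(vals[match(canon, uniq), , drop = FALSE])
  bind_cols(tibble(drug_id = drugs$drug_id), out)
}
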