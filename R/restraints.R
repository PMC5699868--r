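# Cross-link restraint analysis: BS3 Calpha-Calpha distance limits,
# inter/intra classification with abundance filtering of gel-band-resolved
# cross-link tables, interface-residue nomination, and the groove-geometry
# calculation for extended peptides.

#' BS3 Calpha-Calpha distance limits
#'
#' Cross-linked lysine pairs in structures of known geometry sit below
#' 28 Angstrom Calpha-Calpha for most links, and up to 33 Angstrom where
#' local flexibility stretches the reach (cross-linker arm plus two lysine
#' side chains).
#'
#' @param satisfied_max upper bound of the `satisfied` class (Angstrom).
#' @param marginal_max upper bound of the `marginal` class (Angstrom,
#'   inclusive).
#' @return an object of class `restraint_limits`.
#' @export
restraint_limits <- function(satisfied_max = 28, marginal_max = 33) {
  stopifnot(0 < satisfied_max, satisfied_max < marginal_max)
  structure(list(satisfied_max = satisfied_max,
                 marginal_max = marginal_max), class = "restraint_limits")
}

#' Classify a cross-link distance against the BS3 limits
#'
#' `satisfied` below `satisfied_max`, `marginal` in
#' `[satisfied_max, marginal_max]` (closed interval, attributable to local
#' flexibility), `violated` above.
#'
#' @param distance Calpha-Calpha distance(s) in Angstrom, >= 0.
#' @param limits a [restraint_limits()].
#' @return ordered factor with levels `satisfied < marginal < violated`.
#' @export
classify_restraint <- function(distance, limits = restraint_limits()) {
  stopifnot(all(distance >= 0))
  lev <- c("satisfied", "marginal", "violated")
  idx <- 1L + (distance >= limits$satisfied_max) +
    (distance > limits$marginal_max)
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Check lysine-pair distance restraints on a structure
#'
#' For each residue pair the minimum CA-CA distance over the allowed chain
#' assignments is evaluated and classified.  Intra-chain assignments
#' (both residues on the same chain) are always allowed; inter-chain
#' assignments are added when `inter_chain = TRUE`, which is how a link
#' that no single protomer can satisfy is recognized as inter-molecular.
#' Pairs touching a residue with no CA in the structure (e.g. residues in
#' unresolved flexible regions) are reported with class `unmappable`, never
#' dropped.
#'
#' @param model a [structure_model()].
#' @param pairs two-column matrix/data.frame of residue numbers.
#' @param limits a [restraint_limits()].
#' @param inter_chain allow assignments across different chains.
#' @return `data.frame` with columns `res_a`, `res_b`, `distance`,
#'   `class`, `chain_a`, `chain_b`, `assignment` (`intra`/`inter`/`NA`).
#' @export
check_restraints <- function(model, pairs, limits = restraint_limits(),
                             inter_chain = FALSE) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2)
  ca <- model[trimws(model$elety) == "CA", ]
  chains <- unique(ca$chain)
  if (inter_chain && length(chains) < 2) {
    stop("inter-chain assignments need at least 2 chains", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    ra <- pairs[k, 1]; rb <- pairs[k, 2]
    ia <- which(ca$resno == ra)
    ib <- which(ca$resno == rb)
    out <- data.frame(res_a = ra, res_b = rb, distance = NA_real_,
                      class = "unmappable", chain_a = NA_character_,
                      chain_b = NA_character_, assignment = NA_character_)
    if (length(ia) == 0 || length(ib) == 0) return(out)
    combos <- expand.grid(ia = ia, ib = ib)
    same <- ca$chain[combos$ia] == ca$chain[combos$ib]
    keep <- if (inter_chain) rep(TRUE, nrow(combos)) else same
    # a self-pair (same residue number cross-linked to itself) is only
    # meaningful across two protomers, never as the same atom twice
    if (ra == rb) keep <- keep & combos$ia != combos$ib
    combos <- combos[keep, , drop = FALSE]
    if (nrow(combos) == 0) return(out)
    d <- sqrt((ca$x[combos$ia] - ca$x[combos$ib])^2 +
              (ca$y[combos$ia] - ca$y[combos$ib])^2 +
              (ca$z[combos$ia] - ca$z[combos$ib])^2)
    best <- which.min(d)
    out$distance <- d[best]
    out$class <- as.character(classify_restraint(d[best], limits))
    out$chain_a <- ca$chain[combos$ia[best]]
    out$chain_b <- ca$chain[combos$ib[best]]
    out$assignment <- if (out$chain_a == out$chain_b) "intra" else "inter"
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Canonical unordered pair label "a-b" with a <= b.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "-")
}

#' Classify cross-links as inter-molecular and filter by abundance
#'
#' Works on gel-band-resolved cross-link quantification tables (band 1 =
#' monomer band).  A pair is inter-molecular when its monomer-band mean
#' abundance is zero while at least one oligomer band is positive: a link
#' bridging two protomers cannot appear in a covalent monomer.  The
#' abundant subset additionally requires mean abundance of at least
#' `abundance_min` percent in the chosen band (default: the highest-order
#' band).  Row order and duplicated symmetric pairs do not affect the
#' result.
#'
#' @param table long-format cross-link `data.frame` (columns `lys_a`,
#'   `lys_b`, `band`, `mean_pct`, optional `condition`).
#' @param abundance_min abundance threshold in percent.
#' @param band band id used for the abundance filter (default: highest).
#' @param condition if the table carries a `condition` column, which
#'   condition to analyze (default: first in the table).
#' @return list with `inter` and `abundant`, each a `data.frame` of
#'   `lys_a`, `lys_b` (canonical order) plus, for `abundant`, the filter
#'   band abundance.
#' @export
#' @examples
#' cl <- ire1_xlink_table()
#' classify_xlinks(cl, condition = "with_peptides")$abundant  # five pairs
classify_xlinks <- function(table, abundance_min = 1.0, band = NULL,
                            condition = NULL) {
  stopifnot(all(c("lys_a", "lys_b", "band", "mean_pct") %in% names(table)))
  if ("condition" %in% names(table)) {
    if (is.null(condition)) condition <- table$condition[1]
    table <- table[table$condition == condition, ]
  }
  if (nrow(table) == 0) {
    empty <- data.frame(lys_a = integer(), lys_b = integer())
    return(list(inter = empty, abundant = empty))
  }
  if (!1 %in% table$band) {
    stop("monomer band (band 1) missing from table", call. = FALSE)
  }
  if (is.null(band)) band <- max(table$band)
  if (!band %in% table$band) stop("band ", band, " not in table",
                                  call. = FALSE)
  key <- pair_key(table$lys_a, table$lys_b)
  agg <- function(sel) {
    tapply(table$mean_pct[sel], key[sel], mean)
  }
  mono <- agg(table$band == 1)
  oligo_any <- tapply(table$mean_pct[table$band != 1],
                      key[table$band != 1], function(v) any(v > 0))
  filt <- agg(table$band == band)
  keys <- sort(names(mono))
  inter_keys <- keys[mono[keys] == 0 & oligo_any[keys] %in% TRUE]
  abundant_keys <- inter_keys[filt[inter_keys] >= abundance_min]
  to_df <- function(k, ab = NULL) {
    parts <- do.call(rbind, strsplit(k, "-", fixed = TRUE))
    d <- data.frame(lys_a = as.integer(parts[, 1]),
                    lys_b = as.integer(parts[, 2]))
    if (!is.null(ab)) d$band_abundance <- unname(ab)
    d
  }
  list(inter = to_df(inter_keys),
       abundant = to_df(abundant_keys, filt[abundant_keys]))
}

#' Nominate interface residues between two chains
#'
#' Residues of either chain with any heavy atom within `cutoff` Angstrom of
#' the partner chain.  For CA-only models the default cutoff widens to 8
#' Angstrom, since CA-CA separations across a contact exceed the side-chain
#' heavy-atom separations.
#'
#' @param model a [structure_model()].
#' @param chain_a,chain_b chain identifiers.
#' @param cutoff contact cutoff in Angstrom; `NULL` picks 5 (all-atom) or
#'   8 (CA-only).
#' @return list with per-chain integer residue vectors, named by chain.
#' @export
interface_residues <- function(model, chain_a, chain_b, cutoff = NULL) {
  stopifnot(chain_a %in% model$chain, chain_b %in% model$chain,
            chain_a != chain_b)
  heavy <- model[toupper(model$element) != "H", ]
  ca_only <- all(trimws(heavy$elety) == "CA")
  if (is.null(cutoff)) cutoff <- if (ca_only) 8 else 5
  A <- heavy[heavy$chain == chain_a, ]
  B <- heavy[heavy$chain == chain_b, ]
  d2 <- outer(A$x, B$x, "-")^2 + outer(A$y, B$y, "-")^2 +
    outer(A$z, B$z, "-")^2
  contact <- d2 <= cutoff^2
  res <- list(sort(unique(A$resno[rowSums(contact) > 0])),
              sort(unique(B$resno[colSums(contact) > 0])))
  names(res) <- c(chain_a, chain_b)
  res
}

#' Groove geometry for extended peptides
#'
#' @param per_bond_length length contributed per peptide bond in an
#'   extended backbone (Angstrom).
#' @param groove_length length of the peptide-binding groove (Angstrom).
#' @return an object of class `groove_geometry`.
#' @export
groove_geometry <- function(per_bond_length = 3.4, groove_length = 39) {
  stopifnot(per_bond_length > 0, groove_length > 0)
  structure(list(per_bond_length = per_bond_length,
                 groove_length = groove_length), class = "groove_geometry")
}

#' Does an extended peptide fit the binding groove?
#'
#' An n-residue peptide has n - 1 peptide bonds, so its extended length is
#' `(n - 1) * per_bond_length`; it fits when that length does not exceed
#' the groove length.  With the defaults a 12-mer (37.4 Angstrom) fits the
#' 39-Angstrom groove and a 13-mer (40.8 Angstrom) does not.
#'
#' @param n_res peptide length in residues (>= 2).
#' @param geom a [groove_geometry()].
#' @return list with `length` (Angstrom) and `fits` (logical).
#' @export
peptide_fits_groove <- function(n_res, geom = groove_geometry()) {
  stopifnot(n_res >= 2)
  len <- (n_res - 1) * geom$per_bond_length
  list(length = len, fits = len <= geom$groove_length)
}
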