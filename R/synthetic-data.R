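# Synthetic-data generators.
#
# Every downstream module consumes inputs that, for real experiments, come
# from array scanners, plate readers, NMR peak picking, PDB files or
# cross-link quantification.  The generators here emulate each of those
# inputs with known ground truth (injected amino-acid weights, generative
# binding parameters, designated shifted/vanished peaks, ideal-helix
# geometry, designated inter-molecular links) so that recovery of the truth
# by the analysis code is a testable property.

#' Per-amino-acid weight model for synthetic peptide arrays
#'
#' Describes a hypothetical binding preference: each amino acid contributes
#' `weights[aa]` to the log intensity of a spot, and spots carry
#' multiplicative log-normal noise with standard deviation `noise_sd` on the
#' log scale.  Log-normal noise keeps intensities positive, matching
#' fluorescence-scale data.
#'
#' @param weights named numeric vector over the 20 standard amino-acid
#'   letters (missing letters default to 0), dimensionless log-intensity
#'   contributions.
#' @param noise_sd non-negative standard deviation of the log-scale noise.
#' @param seed integer base seed.
#' @return an object of class `aa_weight_model`.
#' @export
#' @examples
#' m <- aa_weight_model(c(W = 0.5, Y = 0.5), noise_sd = 0.2, seed = 1)
aa_weight_model <- function(weights = numeric(), noise_sd = 0.2, seed = 1L) {
  w <- stats::setNames(rep(0, length(AA_LETTERS)), AA_LETTERS)
  if (length(weights) > 0) {
    stopifnot(!is.null(names(weights)))
    bad <- setdiff(names(weights), AA_LETTERS)
    if (length(bad) > 0) {
      stop("unknown amino-acid letters in weights: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    w[names(weights)] <- weights
  }
  stopifnot(all(is.finite(w)), is.finite(noise_sd), noise_sd >= 0)
  structure(list(weights = w, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "aa_weight_model")
}

#' Simulate a peptide tiling array
#'
#' Tiles each input protein sequence into fixed-length peptides (18-mers
#' stepping by 3 residues by default, via [tile_sequence()]) and assigns each
#' spot, in each replicate, the raw intensity
#' `exp(sum of per-residue weights + eps)` with
#' `eps ~ Normal(0, noise_sd^2)`.  Noise is seeded per (spot, replicate)
#' through [derive_seed()], so regenerating a subset of spots reproduces
#' their intensities bit-identically.
#'
#' @param seqs named character vector of protein sequences (names become
#'   protein ids; unnamed inputs get `protein1`, `protein2`, ...).
#' @param model an [aa_weight_model()].
#' @param replicates number of replicate measurements per spot.
#' @param design an [array_design()] giving tile length and step.
#' @return a `data.frame` with columns `spot_id`, `protein_id`,
#'   `start_1based`, `sequence`, `replicate`, `intensity` (the
#'   peptide-array table consumed by the enrichment module).
#' @export
#' @examples
#' tab <- gen_array(c(p1 = strrep("ACDEFGHIKL", 4)),
#'                  aa_weight_model(noise_sd = 0), replicates = 2)
#' head(tab)
gen_array <- function(seqs, model, replicates = 3L, design = array_design()) {
  stopifnot(inherits(model, "aa_weight_model"), replicates >= 1)
  if (is.null(names(seqs))) names(seqs) <- paste0("protein", seq_along(seqs))
  tiles <- do.call(rbind, lapply(names(seqs), function(pid) {
    tl <- tile_sequence(seqs[[pid]], design)
    tl$protein_id <- pid
    tl
  }))
  tiles$spot_id <- sprintf("%s_%04d", tiles$protein_id, tiles$start_1based)
  out <- tiles[rep(seq_len(nrow(tiles)), each = replicates), ]
  out$replicate <- rep(seq_len(replicates), times = nrow(tiles))
  logmu <- vapply(strsplit(out$sequence, ""),
                  function(res) sum(model$weights[res]), numeric(1))
  eps <- mapply(function(sid, rep_i) {
    if (model$noise_sd == 0) return(0)
    set.seed(derive_seed(model$seed, "array", sid, rep_i))
    stats::rnorm(1, 0, model$noise_sd)
  }, out$spot_id, out$replicate)
  out$intensity <- exp(logmu + eps)
  rownames(out) <- NULL
  out[, c("spot_id", "protein_id", "start_1based", "sequence",
          "replicate", "intensity")]
}

#' Simulate a binding titration
#'
#' Draws responses from the log-dose binding isotherm [binding_model()] at
#' the supplied log10 concentrations, adding Gaussian noise.
#'
#' @param params a [binding_params()] object (generative truth).
#' @param x_grid sorted numeric vector (length >= 6) of log10 concentrations
#'   in the same unit used for `logK_half` (micromolar throughout this
#'   package).
#' @param noise_sd standard deviation of additive Gaussian response noise.
#' @param seed integer seed.
#' @return a `data.frame` with columns `x` (log10 concentration) and
#'   `response`.
#' @export
gen_titration <- function(params, x_grid, noise_sd = 0.005, seed = 1L) {
  stopifnot(length(x_grid) >= 6, !is.unsorted(x_grid), all(is.finite(x_grid)))
  mu <- binding_model(x_grid, params)
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, "titration"))
    resp <- mu + stats::rnorm(length(mu), 0, noise_sd)
  } else {
    resp <- mu
  }
  data.frame(x = x_grid, response = resp)
}

#' Simulate a perturbed two-dimensional peak list
#'
#' Starts from a reference peak list and produces a second list in which
#' designated peaks are displaced by given (1H, 13C) offsets and designated
#' peaks are removed; all other peaks keep their positions and heights (an
#' optional log-normal height jitter can be applied).  Emulates the
#' bound-state and point-mutant spectra used for chemical-shift-perturbation
#' analysis and disappearance-based assignment.
#'
#' @param base peak list `data.frame` (columns `label`, `w_C`, `w_H`,
#'   `height`), e.g. from [read_sparky()].
#' @param shifted named list mapping labels to `c(dH, dC)` offsets in ppm.
#' @param vanished character vector of labels to remove.
#' @param height_jitter_sd log-normal sd applied to surviving heights
#'   (default 0, heights preserved).
#' @param seed integer seed.
#' @return list with elements `ref` (the base list) and `test` (the
#'   perturbed list).
#' @export
gen_peaklists <- function(base, shifted = list(), vanished = character(),
                          height_jitter_sd = 0, seed = 1L) {
  stopifnot(all(c("label", "w_C", "w_H", "height") %in% names(base)))
  unknown <- setdiff(c(names(shifted), vanished), base$label)
  if (length(unknown) > 0) {
    stop("labels not present in base peak list: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  test <- base
  for (lab in names(shifted)) {
    i <- which(test$label == lab)
    test$w_H[i] <- test$w_H[i] + shifted[[lab]][1]
    test$w_C[i] <- test$w_C[i] + shifted[[lab]][2]
  }
  test <- test[!(test$label %in% vanished), , drop = FALSE]
  if (height_jitter_sd > 0) {
    set.seed(derive_seed(seed, "peaks"))
    test$height <- test$height *
      exp(stats::rnorm(nrow(test), 0, height_jitter_sd))
  }
  rownames(test) <- NULL
  list(ref = base, test = test)
}

#' Ideal-helix specification
#'
#' Canonical alpha-helix constants by default: 2.3 Angstrom radius,
#' 1.5 Angstrom rise per residue, 100 degrees twist per residue.  Only CA
#' atoms are generated; restraint checking and residue-level SASA
#' normalization operate at CA/residue level.
#'
#' @param n_res number of residues (>= 2).
#' @param radius helix radius in Angstrom.
#' @param rise rise per residue in Angstrom.
#' @param twist twist per residue in degrees.
#' @return an object of class `helix_spec`.
#' @export
helix_spec <- function(n_res, radius = 2.3, rise = 1.5, twist = 100) {
  stopifnot(n_res >= 2, radius >= 0, rise > 0, twist > 0)
  structure(list(n_res = as.integer(n_res), radius = radius,
                 rise = rise, twist = twist), class = "helix_spec")
}

#' Generate an ideal-helix CA trace
#'
#' CA of residue i sits at `(r cos(i*theta), r sin(i*theta), i*rise)`.
#' Residues are numbered 1..n on a single chain "A", residue name ALA.
#'
#' @param spec a [helix_spec()].
#' @param chain chain identifier for the generated atoms.
#' @return a structure model `data.frame` (see [parse_structure()]).
#' @export
#' @examples
#' h <- gen_helix(helix_spec(10))
#' ca_distance(h, c("A", 1), c("A", 2))  # ~3.83 A with defaults
gen_helix <- function(spec, chain = "A") {
  stopifnot(inherits(spec, "helix_spec"))
  i <- seq_len(spec$n_res)
  th <- i * spec$twist * pi / 180
  structure_model(data.frame(
    chain = chain, resno = i, resname = "ALA", elety = "CA",
    element = "C",
    x = spec$radius * cos(th), y = spec$radius * sin(th),
    z = i * spec$rise))
}

#' Simulate a quantified cross-link abundance table
#'
#' Emulates gel-band-resolved cross-link quantification: each lysine pair
#' carries a mean abundance (%) per SDS-PAGE band, band 1 being the monomer
#' band.  Pairs designated inter-molecular get zero abundance in the monomer
#' band and positive abundance in at least one oligomer band; all other
#' pairs are given positive monomer-band abundance.
#'
#' @param pairs two-column matrix or data.frame of lysine residue numbers.
#' @param inter_set logical vector (one per pair) marking designated
#'   inter-molecular links.
#' @param band_count number of gel bands (>= 2); band 1 is the monomer.
#' @param abundance named or unnamed numeric vector of per-pair mean
#'   abundance (%) used in the bands where the pair is present (recycled).
#' @param condition condition label recorded on every row.
#' @param seed integer seed controlling the +/-20% per-band spread.
#' @return a long-format cross-link `data.frame` with columns `lys_a`,
#'   `lys_b`, `band`, `condition`, `mean_pct`, `sd_pct`.
#' @export
gen_xlink_table <- function(pairs, inter_set, band_count = 5L,
                            abundance = 2, condition = "with_peptides",
                            seed = 1L) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2, length(inter_set) == nrow(pairs),
            band_count >= 2)
  abundance <- rep_len(abundance, nrow(pairs))
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    set.seed(derive_seed(seed, "xlink", pairs[k, 1], pairs[k, 2]))
    spread <- stats::runif(band_count, 0.8, 1.2)
    mean_pct <- abundance[k] * spread
    if (inter_set[k]) mean_pct[1] <- 0
    data.frame(lys_a = pairs[k, 1], lys_b = pairs[k, 2],
               band = seq_len(band_count), condition = condition,
               mean_pct = mean_pct, sd_pct = 0.2 * mean_pct)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published IRE1alpha cLD cross-link quantification table
#'
#' The six BS3 cross-linked lysine pairs of the IRE1alpha core lumenal
#' domain quantified per SDS-PAGE band (band 1 = monomer, bands 2-5 =
#' covalent dimers and higher oligomers), with and without bound peptides,
#' shipped as a plain-text fixture under `extdata`.  Five of the six pairs
#' pass the inter-molecular + 1%-abundance filter (see [classify_xlinks()]).
#'
#' @return long-format cross-link `data.frame` (columns `lys_a`, `lys_b`,
#'   `band`, `condition`, `mean_pct`, `sd_pct`).
#' @export
ire1_xlink_table <- function() {
  path <- system.file("extdata", "ire1_cld_xlinks.csv", package = "ire1cld",
                      mustWork = TRUE)
  read_xlink_csv(path)
}
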