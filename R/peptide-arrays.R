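# Peptide tiling-array enrichment analysis.
#
# Arrays tile a protein sequence into overlapping 18-mer spots (3-residue
# step).  After per-replicate max normalization, the top decile of spots by
# mean normalized intensity defines the "binders"; per-amino-acid enrichment
# is the log2 ratio of an amino acid's frequency among binder residues to
# its frequency across the whole array, with significance from replicate
# scatter.

#' Tiling-array design parameters
#'
#' @param tile_length peptide length per spot (residues).
#' @param step shift between adjacent spots (residues).
#' @param top_fraction fraction of spots treated as binders.
#' @param alpha significance level used when flagging enrichments.
#' @return an object of class `array_design`.
#' @export
array_design <- function(tile_length = 18L, step = 3L,
                         top_fraction = 0.10, alpha = 0.05) {
  stopifnot(step > 0, step <= tile_length,
            top_fraction > 0, top_fraction < 1, alpha > 0, alpha < 1)
  structure(list(tile_length = as.integer(tile_length),
                 step = as.integer(step),
                 top_fraction = top_fraction, alpha = alpha),
            class = "array_design")
}

#' Tile a protein sequence into array spots
#'
#' Tiles start at positions 1, 1 + step, ...; the number of tiles is
#' `floor((L - tile_length) / step) + 1`.
#'
#' @param seq protein sequence (single string).
#' @param design an [array_design()].
#' @return `data.frame` with columns `start_1based` and `sequence`.
#' @export
#' @examples
#' tile_sequence(strrep("A", 21))  # two tiles, starts 1 and 4
tile_sequence <- function(seq, design = array_design()) {
  res <- check_sequence(seq)
  L <- length(res)
  if (L < design$tile_length) {
    stop(sprintf("sequence length %d is shorter than the tile length %d",
                 L, design$tile_length), call. = FALSE)
  }
  starts <- seq(1L, L - design$tile_length + 1L, by = design$step)
  data.frame(
    start_1based = starts,
    sequence = vapply(starts, function(s)
      paste(res[s:(s + design$tile_length - 1L)], collapse = ""),
      character(1)))
}

#' Normalize array intensities to the per-replicate maximum
#'
#' Each replicate's spot intensities are divided by the maximum intensity in
#' that replicate, so the brightest spot in every replicate scores 1.  The
#' operation is idempotent and removes any uniform intensity rescaling.
#'
#' @param table peptide-array `data.frame` (see [gen_array()]).
#' @return the table with `intensity` replaced by normalized values.
#' @export
normalize_array <- function(table) {
  stopifnot(all(c("replicate", "intensity") %in% names(table)),
            all(is.finite(table$intensity)), all(table$intensity >= 0))
  for (r in unique(table$replicate)) {
    i <- table$replicate == r
    mx <- max(table$intensity[i])
    if (mx == 0) {
      stop(sprintf("replicate %s has all-zero intensities", r),
           call. = FALSE)
    }
    table$intensity[i] <- table$intensity[i] / mx
  }
  table
}

# Rank spots by a vector of scores and return the top ceil(frac * N)
# spot_ids; ties at the cut broken by (score descending, spot_id ascending).
top_ids <- function(spot_id, score, frac) {
  n_top <- ceiling(frac * length(spot_id))
  ord <- order(-score, spot_id)
  spot_id[ord][seq_len(n_top)]
}

#' Select the top-scoring spots of a normalized array
#'
#' Spots are ranked by mean normalized intensity across replicates and the
#' top `ceil(top_fraction * N)` spots are selected (ceiling guarantees a
#' non-empty set for small arrays).
#'
#' @param table normalized peptide-array `data.frame`.
#' @param design an [array_design()].
#' @return character vector of selected `spot_id`s.
#' @export
select_top <- function(table, design = array_design()) {
  agg <- stats::aggregate(intensity ~ spot_id, data = table, FUN = mean)
  top_ids(agg$spot_id, agg$intensity, design$top_fraction)
}

# Frequency of each amino acid among the residues of the given spot
# sequences (one sequence per spot; replicates must be collapsed first).
aa_freq <- function(sequences) {
  counts <- count_aa(unlist(strsplit(sequences, "")))
  counts / sum(counts)
}

# Enrichment of top-set composition vs whole-array composition for one
# selection.  Zero top-set counts get a 0.5-residue pseudo-count (flagged)
# so depletion stays finite and monotone.
enrichment_one <- function(top_seqs, all_seqs) {
  top_counts <- count_aa(unlist(strsplit(top_seqs, "")))
  all_counts <- count_aa(unlist(strsplit(all_seqs, "")))
  present <- all_counts > 0
  flagged <- present & top_counts == 0
  top_counts[flagged] <- 0.5
  f_top <- top_counts / sum(top_counts)
  f_all <- all_counts / sum(all_counts)
  E <- rep(NA_real_, length(AA_LETTERS))
  names(E) <- AA_LETTERS
  E[present] <- log2(f_top[present] / f_all[present])
  list(E = E, flagged = flagged, present = present)
}

#' Per-amino-acid enrichment in the top-binding spots
#'
#' For each amino acid `a`, computes `E(a) = log2(f_top(a) / f_all(a))`
#' where `f_top` is its frequency among top-set residues and `f_all` its
#' frequency across all array residues.  Occurrences are counted unweighted.
#' With `per_replicate = TRUE` (the default, requires >= 2 replicates) the
#' top decile is re-selected within each replicate, `E` is computed per
#' replicate, the reported `log2_enrichment` is the replicate mean, and the
#' p-value per amino acid is a two-sided one-sample t-test of the replicate
#' `E` values against 0.  With `per_replicate = FALSE` a single pooled
#' selection is used and no p-values are produced.
#'
#' Amino acids absent from the top set are given a 0.5-residue pseudo-count
#' before the ratio (and flagged), so depletions are finite; amino acids
#' absent from the whole array are reported as `NA`.
#'
#' @param table normalized peptide-array `data.frame`.
#' @param design an [array_design()].
#' @param per_replicate compute per-replicate enrichments and p-values.
#' @param per_protein rank spots within each protein separately instead of
#'   pooling across all proteins on the array (pooled is the default).
#' @return an object of class `enrichment_result`: a `data.frame` with
#'   columns `aa`, `log2_enrichment`, `sd`, `p_value`, `flag`, plus
#'   attributes `top_set` (pooled-selection spot ids), `replicate_E`
#'   (amino acid x replicate matrix) and `n_replicates`.
#' @export
aa_enrichment <- function(table, design = array_design(),
                          per_replicate = TRUE, per_protein = FALSE) {
  reps <- sort(unique(table$replicate))
  one_rep <- table[table$replicate == reps[1], ]
  all_seqs <- one_rep$sequence

  select_within <- function(tab) {
    if (per_protein) {
      unlist(lapply(split(tab, tab$protein_id), function(d)
        top_ids(d$spot_id, d$intensity, design$top_fraction)),
        use.names = FALSE)
    } else {
      top_ids(tab$spot_id, tab$intensity, design$top_fraction)
    }
  }

  # pooled selection on the mean across replicates (the reported top set)
  agg <- stats::aggregate(intensity ~ spot_id + protein_id, data = table,
                          FUN = mean)
  top_set <- select_within(agg)
  pooled <- enrichment_one(one_rep$sequence[one_rep$spot_id %in% top_set],
                           all_seqs)

  rep_E <- NULL
  if (per_replicate) {
    if (length(reps) < 2) {
      stop("per-replicate enrichment needs at least 2 replicates",
           call. = FALSE)
    }
    rep_E <- sapply(reps, function(r) {
      tab_r <- table[table$replicate == r, ]
      ids <- select_within(tab_r)
      enrichment_one(tab_r$sequence[tab_r$spot_id %in% ids], all_seqs)$E
    })
    colnames(rep_E) <- paste0("rep", reps)
    est <- rowMeans(rep_E)
    sds <- apply(rep_E, 1, stats::sd)
    pvals <- apply(rep_E, 1, function(e) {
      if (any(is.na(e)) || stats::sd(e) == 0) return(NA_real_)
      stats::t.test(e, mu = 0)$p.value
    })
  } else {
    est <- pooled$E
    sds <- rep(NA_real_, length(est))
    pvals <- rep(NA_real_, length(est))
  }

  out <- data.frame(aa = AA_LETTERS, log2_enrichment = unname(est),
                    sd = unname(sds), p_value = unname(pvals),
                    flag = ifelse(pooled$flagged, "zero_top_count", ""))
  attr(out, "top_set") <- top_set
  attr(out, "replicate_E") <- rep_E
  attr(out, "n_replicates") <- length(reps)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Compare amino-acid preferences of two binding probes
#'
#' Per amino acid, the difference in mean log2 enrichment between two
#' [aa_enrichment()] results (both computed with `per_replicate = TRUE`)
#' and an unpaired two-sided t-test across their replicate enrichment
#' values.  Amino acids absent from either array are dropped with a
#' warning; fewer than 2 replicates on either side leaves the p-value `NA`
#' with a flag.
#'
#' @param resultA,resultB `enrichment_result` objects.
#' @return `data.frame` with columns `aa`, `delta_E` (A minus B),
#'   `p_value`, `flag`.
#' @export
compare_probes <- function(resultA, resultB) {
  EA <- attr(resultA, "replicate_E")
  EB <- attr(resultB, "replicate_E")
  if (is.null(EA) || is.null(EB)) {
    stop("both results must carry per-replicate enrichment values",
         call. = FALSE)
  }
  keep <- !(is.na(rowMeans(EA)) | is.na(rowMeans(EB)))
  if (any(!keep)) {
    warning("amino acids absent from an array excluded from comparison: ",
            paste(AA_LETTERS[!keep], collapse = ", "), call. = FALSE)
  }
  res <- lapply(which(keep), function(i) {
    a <- EA[i, ]; b <- EB[i, ]
    flag <- ""
    if (length(a) < 2 || length(b) < 2) {
      p <- NA_real_; flag <- "too_few_replicates"
    } else if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
      p <- if (mean(a) == mean(b)) 1 else NA_real_
      if (is.na(p)) flag <- "zero_variance"
    } else {
      p <- stats::t.test(a, b, var.equal = FALSE)$p.value
    }
    data.frame(aa = AA_LETTERS[i], delta_E = mean(a) - mean(b),
               p_value = p, flag = flag)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
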