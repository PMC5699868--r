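# Methyl-TROSY peak-list analysis: peak matching, mutation-based
# assignment, combined chemical-shift perturbation (CSP) with category
# thresholds, and paramagnetic relaxation enhancement (PRE) broadening
# profiles normalized by solvent accessibility.

#' CSP category thresholds
#'
#' Combined perturbations are binned by strict thresholds: `none` up to
#' 0.005 ppm, then `slight` (> 0.005), `moderate` (> 0.010) and
#' `significant` (> 0.020).  `alpha_C` is the carbon weight in the combined
#' CSP `sqrt(dH^2 + (alpha_C * dC)^2)`; 0.25 is the standard scaling that
#' puts 13C methyl shifts on the 1H footing.
#'
#' @param slight,moderate,significant threshold values in ppm
#'   (strictly increasing).
#' @param alpha_C carbon weight (dimensionless).
#' @return an object of class `csp_thresholds`.
#' @export
csp_thresholds <- function(slight = 0.005, moderate = 0.010,
                           significant = 0.020, alpha_C = 0.25) {
  stopifnot(0 < slight, slight < moderate, moderate < significant,
            alpha_C > 0)
  structure(list(slight = slight, moderate = moderate,
                 significant = significant, alpha_C = alpha_C),
            class = "csp_thresholds")
}

CSP_LEVELS <- c("none", "slight", "moderate", "significant")

# Category from a combined CSP value; strict inequalities at boundaries.
csp_category <- function(delta_nu, thresholds) {
  cut_idx <- 1L +
    (delta_nu > thresholds$slight) +
    (delta_nu > thresholds$moderate) +
    (delta_nu > thresholds$significant)
  factor(CSP_LEVELS[cut_idx], levels = CSP_LEVELS, ordered = TRUE)
}

#' Match two peak lists by mutual nearest neighbors
#'
#' Peaks are compared in scaled shift space (`dH / tol_H`, `dC / tol_C`);
#' a pair matches when each is the other's nearest neighbor and their
#' scaled distance is at most 1, so every peak joins at most one match.
#'
#' @param ref,test peak list `data.frame`s (columns `label`, `w_C`,
#'   `w_H`, `height`).
#' @param tol_H,tol_C matching tolerances in ppm (defaults reflect
#'   methyl-TROSY linewidths: 0.03 ppm 1H, 0.15 ppm 13C).
#' @return list with `matches` (`data.frame`: `ref_label`, `test_label`,
#'   `dH`, `dC`, `dist`), `unmatched_ref` and `unmatched_test` (label
#'   vectors).
#' @export
match_peaks <- function(ref, test, tol_H = 0.03, tol_C = 0.15) {
  stopifnot(tol_H > 0, tol_C > 0)
  if (nrow(ref) == 0 || nrow(test) == 0) {
    return(list(matches = data.frame(ref_label = character(),
                                     test_label = character(),
                                     dH = numeric(), dC = numeric(),
                                     dist = numeric()),
                unmatched_ref = ref$label, unmatched_test = test$label))
  }
  dH <- outer(ref$w_H, test$w_H, "-")
  dC <- outer(ref$w_C, test$w_C, "-")
  d <- sqrt((dH / tol_H)^2 + (dC / tol_C)^2)
  nn_of_ref <- apply(d, 1, which.min)
  nn_of_test <- apply(d, 2, which.min)
  i <- seq_len(nrow(ref))
  mutual <- nn_of_test[nn_of_ref[i]] == i &
    d[cbind(i, nn_of_ref[i])] <= 1
  mi <- which(mutual)
  matches <- data.frame(
    ref_label = ref$label[mi], test_label = test$label[nn_of_ref[mi]],
    dH = -dH[cbind(mi, nn_of_ref[mi])], dC = -dC[cbind(mi, nn_of_ref[mi])],
    dist = d[cbind(mi, nn_of_ref[mi])])
  list(matches = matches,
       unmatched_ref = ref$label[setdiff(i, mi)],
       unmatched_test = test$label[setdiff(seq_len(nrow(test)),
                                           nn_of_ref[mi])])
}

#' Assign peaks by disappearance in a point-mutant spectrum
#'
#' A peak present in the wild-type spectrum but absent in the spectrum of a
#' point mutant is assigned to the mutated residue; conversely, a peak
#' present only in the mutant (e.g. an engineered X-to-Ile probe) is
#' reported as `appeared`.  More than one vanished peak, or a vanished peak
#' together with an appeared one (a peak that may simply have shifted
#' beyond tolerance), makes the assignment ambiguous; all candidates are
#' returned with the flag set.
#'
#' @param wt,mutant peak list `data.frame`s.
#' @param tol_H,tol_C matching tolerances in ppm.
#' @return list with `vanished`, `appeared` (label vectors) and
#'   `ambiguous` (logical).
#' @export
assign_by_disappearance <- function(wt, mutant, tol_H = 0.03, tol_C = 0.15) {
  m <- match_peaks(wt, mutant, tol_H, tol_C)
  vanished <- m$unmatched_ref
  appeared <- m$unmatched_test
  list(vanished = vanished, appeared = appeared,
       ambiguous = length(vanished) > 1 ||
         (length(vanished) >= 1 && length(appeared) >= 1))
}

#' Combined chemical-shift perturbation for one site
#'
#' `delta_nu = sqrt(dH^2 + (alpha_C * dC)^2)` from the 1H and 13C shift
#' differences of the same site in two spectra, classified by the strict
#' category thresholds.
#'
#' @param ref,bound single-row peak `data.frame`s (or lists with `w_H`,
#'   `w_C`) for the same site in the reference and perturbed spectrum.
#' @param thresholds a [csp_thresholds()].
#' @return one-row `data.frame` with `label`, `delta_H`, `delta_C`,
#'   `delta_nu`, `category`.
#' @export
combined_csp <- function(ref, bound, thresholds = csp_thresholds()) {
  dH <- bound$w_H - ref$w_H
  dC <- bound$w_C - ref$w_C
  dnu <- sqrt(dH^2 + (thresholds$alpha_C * dC)^2)
  data.frame(label = if (!is.null(ref$label)) ref$label else NA_character_,
             delta_H = dH, delta_C = dC, delta_nu = dnu,
             category = csp_category(dnu, thresholds))
}

#' CSP profile between two peak lists
#'
#' Matches the lists (by label when both are fully labeled with a common
#' label set, otherwise by mutual-nearest-neighbor position matching) and
#' computes the combined CSP and category for every matched site.
#' Unassigned fingerprint spectra are therefore supported: positions alone
#' suffice, and [csp_category_counts()] summarizes them as per-category
#' counts.
#'
#' @param ref,bound peak list `data.frame`s.
#' @param thresholds a [csp_thresholds()].
#' @param tol_H,tol_C tolerances for positional matching.
#' @param by_label force label-based (`TRUE`) or positional (`FALSE`)
#'   matching; default `NULL` chooses label matching when every `ref`
#'   label occurs in `bound`.
#' @return `data.frame` of per-site CSP records sorted by decreasing
#'   `delta_nu`.
#' @export
csp_profile <- function(ref, bound, thresholds = csp_thresholds(),
                        tol_H = 0.03, tol_C = 0.15, by_label = NULL) {
  if (is.null(by_label)) {
    by_label <- !anyNA(ref$label) && !anyNA(bound$label) &&
      all(ref$label %in% bound$label)
  }
  if (by_label) {
    pairs <- data.frame(ref_i = seq_len(nrow(ref)),
                        bound_i = match(ref$label, bound$label))
    pairs <- pairs[!is.na(pairs$bound_i), ]
  } else {
    m <- match_peaks(ref, bound, tol_H, tol_C)$matches
    pairs <- data.frame(ref_i = match(m$ref_label, ref$label),
                        bound_i = match(m$test_label, bound$label))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k)
    combined_csp(ref[pairs$ref_i[k], ], bound[pairs$bound_i[k], ],
                 thresholds)))
  out <- out[order(-out$delta_nu), ]
  rownames(out) <- NULL
  out
}

#' Count CSP categories
#'
#' @param profile output of [csp_profile()].
#' @return named integer vector over the four categories.
#' @export
csp_category_counts <- function(profile) {
  table(factor(profile$category, levels = CSP_LEVELS))
}

#' PRE broadening profile normalized by solvent accessibility
#'
#' For every reference peak matched in the spin-label spectrum the
#' intensity ratio `I_PRE / I_0` is computed (reference peaks with no
#' partner are treated as erased: ratio 0, the strongest broadening).
#' Each site's maximum solvent-accessible surface area is normalized to the
#' per-site maximum (`sasa_frac = sasa / max(sasa)`) and multiplied with
#' the ratio, damping apparent broadening at buried sites that cannot see
#' the spin label non-specifically.  Records are sorted ascending by the
#' normalized value, most broadened first.
#'
#' Both spectra must be acquired and scaled comparably: ratios are only
#' meaningful when reference and PRE spectrum share an intensity scale.
#'
#' @param ref,pre peak list `data.frame`s (reference and spin-labeled
#'   sample).
#' @param sasa named numeric vector, label to solvent-accessible area in
#'   square Angstrom; must cover every matched label.
#' @param tol_H,tol_C matching tolerances in ppm.
#' @param invert use the inverse convention `I_0 / I_PRE` instead of the
#'   default `I_PRE / I_0` (erased peaks then get `Inf`).
#' @return `data.frame` with columns `label`, `I_PRE`, `I_0`, `ratio`,
#'   `sasa_frac`, `normalized_pre`.
#' @export
pre_profile <- function(ref, pre, sasa, tol_H = 0.03, tol_C = 0.15,
                        invert = FALSE) {
  stopifnot(all(sasa >= 0), max(sasa) > 0)
  m <- match_peaks(ref, pre, tol_H, tol_C)
  labels <- ref$label
  missing_sasa <- setdiff(labels, names(sasa))
  if (length(missing_sasa) > 0) {
    stop("no SASA value for label(s): ",
         paste(missing_sasa, collapse = ", "), call. = FALSE)
  }
  I0 <- ref$height
  stopifnot(all(I0 > 0))
  Ipre <- rep(0, length(labels))
  hit <- match(m$matches$ref_label, labels)
  Ipre[hit] <- pre$height[match(m$matches$test_label, pre$label)]
  ratio <- if (invert) I0 / Ipre else Ipre / I0
  sasa_frac <- unname(sasa[labels] / max(sasa[labels]))
  out <- data.frame(label = labels, I_PRE = Ipre, I_0 = I0, ratio = ratio,
                    sasa_frac = sasa_frac,
                    normalized_pre = ratio * sasa_frac)
  out <- out[order(out$normalized_pre, out$label), ]
  rownames(out) <- NULL
  out
}
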