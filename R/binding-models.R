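# Binding-isotherm fitting.
#
# Titrations (fluorescence anisotropy or min-max-normalized thermophoresis
# response against log10 protein concentration) are fitted with the
# log-dose logistic
#
#   response(x) = r_free + (r_max - r_free) / (1 + 10^((logK_half - x) * n_H))
#
# where x is log10 concentration (micromolar throughout), r_free/r_max are
# the plateau responses, n_H the Hill coefficient and 10^logK_half the
# apparent half-saturation concentration K_half.  K_half is an apparent
# constant, not a dissociation constant: when several oligomerization
# equilibria superimpose on binding the isotherm scores them jointly.

#' Parameters of the log-dose binding isotherm
#'
#' @param r_free response at the free (low-concentration) plateau.
#' @param r_max response at the saturated plateau.
#' @param K_half apparent half-saturation concentration in micromolar
#'   (stored as `logK_half = log10(K_half)`); supply either `K_half` or
#'   `logK_half`.
#' @param logK_half log10 of `K_half` (micromolar).
#' @param n_H Hill coefficient (> 0).
#' @return an object of class `binding_params`.
#' @export
#' @examples
#' binding_params(r_free = 0.05, r_max = 0.25, K_half = 24)
binding_params <- function(r_free, r_max, K_half = NULL, logK_half = NULL,
                           n_H = 1) {
  if (is.null(logK_half)) {
    stopifnot(!is.null(K_half), K_half > 0)
    logK_half <- log10(K_half)
  }
  stopifnot(is.finite(r_free), is.finite(r_max), is.finite(logK_half),
            n_H > 0)
  structure(list(r_free = r_free, r_max = r_max, logK_half = logK_half,
                 n_H = n_H), class = "binding_params")
}

#' Evaluate the log-dose binding isotherm
#'
#' @param x log10 concentration (micromolar), any numeric vector.
#' @param params a [binding_params()] object.
#' @return predicted response; strictly increasing in `x` when
#'   `r_max > r_free`.
#' @export
#' @examples
#' p <- binding_params(0.05, 0.25, K_half = 24)
#' binding_model(log10(24), p)  # midpoint: (0.05 + 0.25) / 2
binding_model <- function(x, params) {
  params$r_free + (params$r_max - params$r_free) /
    (1 + 10^((params$logK_half - x) * params$n_H))
}

# Residual function over the free-parameter vector; `fixed` is a named
# logical mask over c("r_free", "r_max", "logK_half", "n_H").
fit_residuals <- function(free, fixed_vals, free_names, x, y) {
  p <- fixed_vals
  p[free_names] <- free
  y - binding_model(x, structure(as.list(p), class = "binding_params"))
}

#' Fit a titration with the log-dose binding isotherm
#'
#' Levenberg-Marquardt least squares (via [minpack.lm::nls.lm()]) with
#' deterministic multistart: 5 starting values of `logK_half` spanning the
#' sampled concentration range, `n_H = 1`, plateaus from the data extremes.
#' Default bounds keep `n_H` in [0.3, 5] and the plateaus within the data
#' range +/- 50% of its span ("minimal constraints" that prevent
#' plateau/K trade-off blow-ups).  Any subset of parameters can be fixed
#' (e.g. `fixed = c(r_max = 0.25)` for weak binders whose upper plateau is
#' not reached).
#'
#' A fitted `K_half` more than 10-fold outside the sampled concentration
#' range is reported with an `extrapolated` warning flag; non-convergence is
#' flagged, never silent; a flat response is an error ("no binding
#' signal").
#'
#' @param data `data.frame` with columns `x` (log10 concentration,
#'   micromolar) and `response`, >= 6 points.
#' @param init optional [binding_params()] used as the single start.
#' @param fixed optional named numeric vector fixing parameters at the
#'   given values (names among `r_free`, `r_max`, `logK_half`, `n_H`).
#' @param n_H_bounds,plateau_pad bound controls (see details above).
#' @return an object of class `binding_fit`: list with `params`
#'   ([binding_params()]), `K_half`, `se` (named, delta-method SE for
#'   `K_half` under `se["K_half"]`), `r_squared`, `converged`, `flags`
#'   (character vector), `fixed` (names of fixed parameters), `fitted`,
#'   `residuals`, `data`.
#' @export
fit_binding <- function(data, init = NULL, fixed = NULL,
                        n_H_bounds = c(0.3, 5), plateau_pad = 0.5) {
  stopifnot(all(c("x", "response") %in% names(data)),
            all(is.finite(data$x)), all(is.finite(data$response)))
  if (nrow(data) < 6) stop("need at least 6 titration points", call. = FALSE)
  x <- data$x
  y <- data$response
  span <- diff(range(y))
  if (span == 0) stop("no binding signal: response is flat", call. = FALSE)

  par_names <- c("r_free", "r_max", "logK_half", "n_H")
  fixed_vals <- stats::setNames(rep(NA_real_, 4), par_names)
  if (!is.null(fixed)) {
    stopifnot(all(names(fixed) %in% par_names), all(is.finite(fixed)))
    fixed_vals[names(fixed)] <- fixed
  }
  free_names <- par_names[is.na(fixed_vals)]
  if (length(free_names) == 0) stop("all parameters fixed", call. = FALSE)

  lower <- c(r_free = min(y) - plateau_pad * span,
             r_max = min(y) - plateau_pad * span,
             logK_half = min(x) - 2, n_H = n_H_bounds[1])
  upper <- c(r_free = max(y) + plateau_pad * span,
             r_max = max(y) + plateau_pad * span,
             logK_half = max(x) + 2, n_H = n_H_bounds[2])

  starts <- if (!is.null(init)) {
    list(unlist(init[par_names]))
  } else {
    lapply(seq(min(x), max(x), length.out = 5), function(lk)
      c(r_free = min(y), r_max = max(y), logK_half = lk, n_H = 1))
  }

  best <- NULL
  for (st in starts) {
    st_free <- pmin(pmax(st[free_names], lower[free_names]),
                    upper[free_names])
    res <- try(minpack.lm::nls.lm(
      par = st_free, lower = lower[free_names], upper = upper[free_names],
      fn = fit_residuals, fixed_vals = fixed_vals, free_names = free_names,
      x = x, y = y,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-15, ptol = 1e-15, maxiter = 500)), silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop("binding fit failed from every start", call. = FALSE)

  flags <- character()
  converged <- best$info %in% 1:4
  if (!converged) flags <- c(flags, "not_converged")

  est <- fixed_vals
  est[free_names] <- best$par
  params <- structure(as.list(est), class = "binding_params")
  K_half <- 10^est[["logK_half"]]

  conc_range <- 10^range(x)
  if (K_half < conc_range[1] / 10 || K_half > conc_range[2] * 10) {
    flags <- c(flags, "extrapolated")
  }

  # SEs from the local quadratic approximation (J'J), free parameters only
  n <- length(y); p <- length(free_names)
  se <- stats::setNames(rep(NA_real_, 4), par_names)
  if (n > p) {
    s2 <- best$deviance / (n - p)
    vc <- try(solve(best$hessian) * s2, silent = TRUE)
    if (!inherits(vc, "try-error") && all(diag(vc) >= 0)) {
      se[free_names] <- sqrt(diag(vc))
    }
  }
  se_K <- unname(K_half * log(10) * se[["logK_half"]])

  fitted <- binding_model(x, params)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)

  structure(list(
    params = params, K_half = unname(K_half),
    se = c(se, K_half = se_K), r_squared = r2, converged = converged,
    flags = flags, fixed = names(fixed), fitted = fitted,
    residuals = y - fitted, data = data), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "Binding fit: K_half = %.4g uM (SE %.3g), n_H = %.3g, R^2 = %.4f\n",
    x$K_half, x$se[["K_half"]], x$params$n_H, x$r_squared))
  if (length(x$flags) > 0) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Min-max normalize a thermophoresis (MST) response column
#'
#' Scales responses to [0, 1] so MST titrations are fitted on the same
#' footing as anisotropy data.
#'
#' @param data titration `data.frame` with a `response` column.
#' @return the data with `response` rescaled.
#' @export
normalize_mst <- function(data) {
  rng <- range(data$response)
  if (diff(rng) == 0) stop("no binding signal: response is flat",
                           call. = FALSE)
  data$response <- (data$response - rng[1]) / diff(rng)
  data
}

#' Summarize a labeled series of binding fits
#'
#' Tabulates apparent affinities and fold-changes relative to a designated
#' reference.  Fold-change is the affinity gain `K_ref / K`, so a
#' tighter-binding construct shows a fold-change above 1.
#'
#' @param fits named list of `binding_fit` objects.
#' @param reference label of the reference fit (default: the first).
#' @return `data.frame` with columns `label`, `K_half`, `se`,
#'   `fold_change`, `r_squared`, `flags`.
#' @export
series_summary <- function(fits, reference = names(fits)[1]) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)),
            reference %in% names(fits))
  K_ref <- fits[[reference]]$K_half
  out <- do.call(rbind, lapply(names(fits), function(lab) {
    f <- fits[[lab]]
    data.frame(label = lab, K_half = f$K_half, se = f$se[["K_half"]],
               fold_change = K_ref / f$K_half, r_squared = f$r_squared,
               flags = paste(f$flags, collapse = ";"))
  }))
  rownames(out) <- NULL
  out
}
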