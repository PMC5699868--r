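test_that("isotherm evaluates to its closed-form landmarks", {
  p <- binding_params(0.05, 0.25, K_half = 24)
  expect_equal(binding_model(log10(24), p), 0.15)
  expect_equal(binding_model(-20, p), 0.05, tolerance = 1e-12)
  expect_equal(binding_model(20, p), 0.25, tolerance = 1e-12)
  # 10^(log 24 - log 72) = 1/3 => 0.05 + 0.2 / (4/3) = 0.20
  expect_equal(binding_model(log10(72), p), 0.20)
  # strict monotonicity when r_max > r_free
  x <- seq(-3, 4, by = 0.05)
  expect_true(all(diff(binding_model(x, p)) > 0))
})

test_that("noiseless data are recovered exactly", {
  p <- binding_params(0.05, 0.25, K_half = 24, n_H = 1.3)
  f <- fit_binding(gen_titration(p, log_grid(0.1, 500), 0))
  expect_true(max(abs(f$residuals)) < 1e-10)
  expect_equal(f$K_half, 24, tolerance = 1e-6)
  expect_equal(f$params$n_H, 1.3, tolerance = 1e-6)
  expect_true(f$converged)
  expect_gt(f$r_squared, 0.999999)
})

test_that("fit cost never exceeds the cost at the generating truth", {
  xg <- log_grid(0.1, 500)
  for (s in 1:10) {
    p <- binding_params(0.05, 0.25, K_half = 24)
    d <- gen_titration(p, xg, 0.005, seed = s)
    f <- fit_binding(d)
    ss_fit <- sum(f$residuals^2)
    ss_true <- sum((d$response - binding_model(d$x, p))^2)
    expect_lte(ss_fit, ss_true + 1e-12)
  }
})

test_that("changing concentration units rescales K_half exactly", {
  p <- binding_params(0.05, 0.25, K_half = 24)
  d_uM <- gen_titration(p, log_grid(0.1, 500), 0.005, seed = 3)
  d_nM <- d_uM; d_nM$x <- d_nM$x + 3  # uM -> nM
  expect_equal(fit_binding(d_nM)$K_half / fit_binding(d_uM)$K_half, 1000,
               tolerance = 1e-6)
})

test_that("recovery is unbiased and the SE interval calibrated", {
  cases <- list(c(0.456, 0.005, 50), c(5, 0.05, 200), c(16, 0.1, 500),
                c(24, 0.1, 500), c(29.2, 0.1, 500))
  for (cs in cases) {
    K <- cs[1]
    xg <- log_grid(cs[2], cs[3])
    p <- binding_params(0.05, 0.25, K_half = K)
    res <- vapply(1:100, function(i) {
      f <- fit_binding(gen_titration(p, xg, 0.005,
                                     seed = derive_seed(11, K, i)))
      c(f$K_half,
        abs(log10(f$K_half) - log10(K)) <= 1.96 * f$se[["logK_half"]])
    }, numeric(2))
    expect_lt(abs(stats::median(res[1, ]) / K - 1), 0.10,
              label = paste("median bias at K =", K))
    expect_gte(mean(res[2, ]), 0.85)
    expect_lte(mean(res[2, ]), 0.99)
  }
})

test_that("weak binders are recoverable with a fixed upper plateau", {
  xg <- log_grid(0.1, 500)
  p <- binding_params(0.05, 0.25, K_half = 377)
  f <- fit_binding(gen_titration(p, xg, 0.005, seed = 4),
                   fixed = c(r_max = 0.25))
  expect_lt(abs(log2(f$K_half / 377)), 1)  # within 2-fold
  # truth far beyond the titrated range gets the extrapolation flag
  pfar <- binding_params(0.05, 0.25, K_half = 2e4)
  ffar <- fit_binding(gen_titration(pfar, xg, 0.001, seed = 5),
                      fixed = c(r_max = 0.25, n_H = 1))
  expect_true("extrapolated" %in% ffar$flags)
})

test_that("degenerate titrations are rejected", {
  flat <- data.frame(x = log_grid(0.1, 500, 8), response = rep(0.1, 8))
  expect_error(fit_binding(flat), "no binding signal")
  expect_error(fit_binding(data.frame(x = 1:3, response = c(1, 2, 3))),
               "at least 6")
})

test_that("series summaries report affinity fold-changes and flags", {
  xg <- log_grid(0.005, 500, 20)
  mk <- function(K) fit_binding(gen_titration(
    binding_params(0.05, 0.25, K_half = K), xg, 0.002, seed = round(K * 7)))
  fits <- list(`MPZ1-N` = mk(16), `MPZ1-N-2X` = mk(0.456))
  s1 <- series_summary(fits["MPZ1-N"])
  expect_equal(s1$fold_change, 1)
  s <- series_summary(fits, reference = "MPZ1-N")
  # tandem repeat binds an order of magnitude tighter (~35x)
  expect_equal(s$fold_change[s$label == "MPZ1-N-2X"], 16 / 0.456,
               tolerance = 0.15)
  fits$`MPZ1-N`$flags <- "extrapolated"
  s2 <- series_summary(fits)
  expect_match(s2$flags[s2$label == "MPZ1-N"], "extrapolated")
})

test_that("MST normalization puts responses on the unit interval", {
  d <- data.frame(x = log_grid(0.2, 1000, 8),
                  response = c(820, 830, 860, 920, 980, 1010, 1025, 1030))
  n <- normalize_mst(d)
  expect_equal(range(n$response), c(0, 1))
})
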