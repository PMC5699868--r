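test_that("peak matching is mutual-nearest-neighbor within tolerance", {
  pk <- toy_peaks()
  m <- match_peaks(pk, pk)
  expect_equal(nrow(m$matches), nrow(pk))
  expect_true(all(m$matches$dist == 0))
  expect_length(m$unmatched_ref, 0)

  # a ref peak with no partner within tolerance is reported unmatched
  shifted <- pk
  shifted$w_H[shifted$label == "I124"] <- shifted$w_H[2] + 1
  m2 <- match_peaks(pk, shifted)
  expect_true("I124" %in% m2$unmatched_ref)

  # two ref peaks near one test peak: only the mutual nearest matches
  ref <- data.frame(label = c("a", "b"), w_C = c(10.00, 10.05),
                    w_H = c(0.500, 0.512), height = 1)
  test <- data.frame(label = "t", w_C = 10.01, w_H = 0.501, height = 1)
  m3 <- match_peaks(ref, test)
  # brute force: "t" is nearest to "a" in scaled space
  d <- sqrt(((ref$w_H - test$w_H) / 0.03)^2 + ((ref$w_C - test$w_C) / 0.15)^2)
  expect_equal(m3$matches$ref_label, ref$label[which.min(d)])
  expect_equal(m3$unmatched_ref, ref$label[which.max(d)])
})

test_that("disappearance-based assignment handles all mutant outcomes", {
  pk <- toy_peaks()
  minus <- pk[pk$label != "I128", ]
  expect_equal(assign_by_disappearance(pk, minus)$vanished, "I128")

  plus <- rbind(pk, data.frame(label = "T159I", w_C = 9.0, w_H = 0.45,
                               height = 0.4))
  a2 <- assign_by_disappearance(pk, plus)
  expect_equal(a2$appeared, "T159I")
  expect_false(a2$ambiguous)

  moved <- pk
  moved$w_C[moved$label == "I263"] <- moved$w_C[moved$label == "I263"] + 2
  a3 <- assign_by_disappearance(pk, moved)
  expect_true(a3$ambiguous)
  expect_equal(a3$vanished, "I263")
  expect_equal(a3$appeared, "I263")
})

test_that("combined CSP uses strict thresholds and is symmetric", {
  th <- csp_thresholds()
  mk <- function(dH, dC) {
    ref <- data.frame(label = "x", w_C = 10, w_H = 0.5, height = 1)
    bnd <- ref; bnd$w_H <- bnd$w_H + dH; bnd$w_C <- bnd$w_C + dC
    list(ref = ref, bnd = bnd)
  }
  same <- mk(0, 0)
  r0 <- combined_csp(same$ref, same$bnd, th)
  expect_equal(r0$delta_nu, 0)
  expect_equal(as.character(r0$category), "none")

  r1 <- combined_csp(mk(0.021, 0)$ref, mk(0.021, 0)$bnd, th)
  expect_equal(r1$delta_nu, 0.021)
  expect_equal(as.character(r1$category), "significant")

  # boundary is strict: exactly the threshold stays in the lower class
  expect_equal(as.character(ire1cld:::csp_category(th$slight, th)), "none")
  expect_equal(as.character(ire1cld:::csp_category(th$significant, th)),
               "moderate")
  r2 <- combined_csp(mk(0.004, 0)$ref, mk(0.004, 0)$bnd, th)
  expect_equal(as.character(r2$category), "none")

  # swap invariance
  pr <- mk(0.013, -0.02)
  expect_equal(combined_csp(pr$ref, pr$bnd, th)$delta_nu,
               combined_csp(pr$bnd, pr$ref, th)$delta_nu)

  # category is monotone in delta_nu
  dnus <- sort(stats::runif(50, 0, 0.03))
  cats <- ire1cld:::csp_category(dnus, th)
  expect_true(all(diff(as.integer(cats)) >= 0))
})

test_that("CSP classification recovers the generator's shifted set", {
  base <- toy_peaks()
  for (s in 1:5) {
    set.seed(s)
    shift_labels <- sample(base$label, 2)
    shifts <- lapply(shift_labels, function(l)
      c(stats::runif(1, 0.008, 0.02), stats::runif(1, 0.02, 0.06)))
    names(shifts) <- shift_labels
    pl <- gen_peaklists(base, shifted = shifts, seed = s)
    prof <- csp_profile(pl$ref, pl$test, by_label = TRUE)
    flagged <- prof$label[prof$category > "none"]
    expect_setequal(flagged, shift_labels)
  }
})

test_that("PRE profile ranks erased and broadened probes first", {
  base <- toy_peaks()
  pre <- base
  pre$height[pre$label == "I124"] <- 0.5 * pre$height[pre$label == "I124"]
  pre <- pre[pre$label != "L186I", ]  # erased by the spin label
  sasa_map <- c(I52 = 20, I124 = 48, I128 = 5, I263 = 60, L186I = 120)
  prof <- pre_profile(base, pre, sasa_map)
  expect_equal(prof$label[1], "L186I")
  expect_equal(prof$ratio[prof$label == "L186I"], 0)
  expect_equal(prof$normalized_pre[prof$label == "L186I"], 0)
  expect_equal(prof$ratio[prof$label == "I124"], 0.5)
  expect_equal(prof$sasa_frac[prof$label == "I263"], 0.5)
  expect_equal(prof$normalized_pre[prof$label == "I124"], 0.5 * 48 / 120)
  # unity case: unchanged intensity at the most exposed site
  prof_same <- pre_profile(base, base, sasa_map)
  expect_equal(prof_same$normalized_pre[prof_same$label == "L186I"], 1)

  # consistent rescaling of both spectra leaves the ranking unchanged
  base2 <- base; base2$height <- base2$height * 3
  pre2 <- pre; pre2$height <- pre2$height * 3
  expect_equal(pre_profile(base2, pre2, sasa_map)$normalized_pre,
               prof$normalized_pre)

  expect_error(pre_profile(base, pre, sasa_map[-2]), "I124")
})

test_that("peak lists round-trip through the Sparky format", {
  pk <- toy_peaks()
  path <- withr::local_tempfile(fileext = ".list")
  write_sparky(pk, path)
  back <- read_sparky(path)
  expect_equal(back$label, pk$label)
  expect_equal(back$w_C, pk$w_C, tolerance = 1e-4)
  expect_equal(back$w_H, pk$w_H, tolerance = 1e-4)
})
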