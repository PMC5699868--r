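test_that("tiling follows the 18/3 design", {
  expect_equal(nrow(tile_sequence(rand_seq(18, 1))), 1)
  t21 <- tile_sequence(rand_seq(21, 1))
  expect_equal(t21$start_1based, c(1, 4))
  expect_equal(nrow(tile_sequence(rand_seq(248, 1))), 77)
  expect_error(tile_sequence(rand_seq(17, 1)), "shorter")
})

test_that("normalization is per replicate, idempotent and scale-invariant", {
  tab <- data.frame(spot_id = rep(c("a", "b", "c"), 2),
                    protein_id = "p", start_1based = 1,
                    sequence = "X", replicate = rep(1:2, each = 3),
                    intensity = c(2, 4, 8, 1, 5, 10))
  tab$sequence <- rand_seq(18, 2)
  n1 <- normalize_array(tab)
  expect_equal(n1$intensity[1:3], c(0.25, 0.5, 1.0))
  expect_equal(max(n1$intensity[n1$replicate == 2]), 1)
  expect_equal(normalize_array(n1), n1)              # idempotence
  tab2 <- tab; tab2$intensity <- tab2$intensity * 37 # uniform rescale
  expect_equal(normalize_array(tab2), n1)
  tab$intensity[tab$replicate == 1] <- 0
  expect_error(normalize_array(tab), "all-zero")
})

test_that("top selection uses ceiling and deterministic tie-breaks", {
  mk <- function(ints) data.frame(
    spot_id = sprintf("s%02d", seq_along(ints)), protein_id = "p",
    start_1based = seq_along(ints), sequence = rand_seq(18, 3),
    replicate = 1, intensity = ints)
  expect_equal(select_top(mk(1:10)), "s10")
  expect_length(select_top(mk(seq_len(77))), 8)  # ceil(7.7)
  expect_equal(select_top(mk(rep(1, 10))), "s01")  # ties: spot_id ascending
})

test_that("enrichment matches a literal residue-counting oracle", {
  for (s in 1:5) {
    seqv <- rand_seq(18 + 3 * 14, s)  # 15 spots
    tab <- normalize_array(gen_array(c(p = seqv),
                                     aa_weight_model(noise_sd = 0.3,
                                                     seed = s), 1))
    e <- aa_enrichment(tab, per_replicate = FALSE)
    top <- attr(e, "top_set")
    # brute force: count letters one by one
    top_res <- unlist(strsplit(tab$sequence[tab$spot_id %in% top], ""))
    all_res <- unlist(strsplit(tab$sequence, ""))
    present <- unique(all_res)
    denom <- length(top_res) + 0.5 * sum(!present %in% top_res)
    for (aa in present) {
      n_top <- sum(top_res == aa)
      if (n_top == 0) n_top <- 0.5  # pseudo-count for flagged depletions
      f_top <- n_top / denom
      f_all <- sum(all_res == aa) / length(all_res)
      expect_equal(e$log2_enrichment[e$aa == aa], log2(f_top / f_all),
                   tolerance = 1e-12, label = paste("aa", aa, "seed", s))
    }
    # composition frequencies sum to one by construction
    expect_equal(sum(2^e$log2_enrichment[!is.na(e$log2_enrichment)] *
                       ire1cld:::aa_freq(tab$sequence)[
                         !is.na(e$log2_enrichment)]), 1, tolerance = 1e-9)
  }
})

test_that("a top set with the array's composition has zero enrichment", {
  seqv <- rand_seq(18, 1)
  # all spots identical: any top set matches the array composition
  tab <- data.frame(spot_id = sprintf("s%d", 1:10), protein_id = "p",
                    start_1based = 1, sequence = seqv, replicate = 1,
                    intensity = 10:1)
  e <- aa_enrichment(normalize_array(tab), per_replicate = FALSE)
  present <- !is.na(e$log2_enrichment) & e$flag == ""
  expect_true(all(abs(e$log2_enrichment[present]) < 1e-12))
})

test_that("injected preferences are recovered with significance", {
  model <- aa_weight_model(c(C = 0.5, Y = 0.5, W = 0.5, R = 0.5,
                             D = -0.5, E = -0.5), noise_sd = 0.2, seed = 3)
  seqs <- setNames(lapply(1:3, function(i) rand_seq(300, 100 + i)),
                   paste0("p", 1:3))
  tab <- normalize_array(gen_array(unlist(seqs), model, 3))
  e <- aa_enrichment(tab)
  up <- e[e$aa %in% c("C", "Y", "W", "R"), ]
  down <- e[e$aa %in% c("D", "E"), ]
  expect_true(all(up$log2_enrichment > 0 & up$p_value < 0.05))
  expect_true(all(down$log2_enrichment < 0 & down$p_value < 0.05))
})

test_that("probe comparison flags differential preferences", {
  e <- aa_enrichment(normalize_array(gen_array(
    c(p = rand_seq(300, 9)),
    aa_weight_model(c(W = 0.5), noise_sd = 0.2, seed = 1), 3)))
  cmp_same <- compare_probes(e, e)
  expect_true(all(abs(cmp_same$delta_E) < 1e-12))
  expect_true(all(cmp_same$p_value[!is.na(cmp_same$p_value)] > 0.999))

  # probe A tolerates proline, probe B is averse
  seqs <- setNames(lapply(1:3, function(i) rand_seq(300, 200 + i)),
                   paste0("p", 1:3))
  base_w <- c(W = 0.5, Y = 0.5)
  eA <- aa_enrichment(normalize_array(gen_array(
    unlist(seqs), aa_weight_model(base_w, 0.2, seed = 11), 3)))
  eB <- aa_enrichment(normalize_array(gen_array(
    unlist(seqs), aa_weight_model(c(base_w, P = -0.8), 0.2, seed = 12), 3)))
  cmp <- compare_probes(eA, eB)
  pr <- cmp[cmp$aa == "P", ]
  expect_true(pr$delta_E > 0 && pr$p_value < 0.05)
})
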