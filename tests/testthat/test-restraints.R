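test_that("restraint classification respects the BS3 limits", {
  expect_equal(as.character(classify_restraint(27)), "satisfied")
  expect_equal(as.character(classify_restraint(30)), "marginal")
  expect_equal(as.character(classify_restraint(40)), "violated")
  # boundary convention: [28, 33] is marginal (closed interval)
  expect_equal(as.character(classify_restraint(c(28, 33))),
               c("marginal", "marginal"))
  # total and monotone in distance
  d <- sort(stats::runif(100, 0, 60))
  cls <- classify_restraint(d)
  expect_true(all(diff(as.integer(cls)) >= 0))
  expect_false(anyNA(cls))
})

test_that("restraint checking minimizes over allowed chain assignments", {
  dimer <- helix_dimer(40, offset = 10)
  # brute-force the minimum distance for a pair across both chains
  brute <- function(ra, rb, inter) {
    ca <- dimer[trimws(dimer$elety) == "CA", ]
    best <- Inf
    for (i in which(ca$resno == ra)) for (j in which(ca$resno == rb)) {
      if (!inter && ca$chain[i] != ca$chain[j]) next
      if (ra == rb && i == j) next
      best <- min(best, sqrt(sum((
        c(ca$x[i], ca$y[i], ca$z[i]) - c(ca$x[j], ca$y[j], ca$z[j]))^2)))
    }
    best
  }
  pairs <- cbind(c(1, 5, 12, 7), c(30, 25, 12, 39))
  for (inter in c(FALSE, TRUE)) {
    res <- check_restraints(dimer, pairs, inter_chain = inter)
    for (k in seq_len(nrow(pairs))) {
      bf <- brute(pairs[k, 1], pairs[k, 2], inter)
      if (is.finite(bf)) {
        expect_equal(res$distance[k], bf, tolerance = 1e-9)
      } else {
        # no allowed atom assignment (self pair, intra-only): reported NA
        expect_true(is.na(res$distance[k]))
        expect_equal(as.character(res$class[k]), "unmappable")
      }
    }
  }

  # antiparallel dimer: a pair joining opposite chain ends is satisfiable
  # only across chains
  h1 <- gen_helix(helix_spec(40), chain = "A")
  h2 <- gen_helix(helix_spec(40), chain = "B")
  h2$z <- 41 * 1.5 - h2$z  # flip chain B head-to-tail
  h2$x <- h2$x + 10
  anti <- structure_model(rbind(h1, h2))
  res_intra <- check_restraints(anti, cbind(1, 40), inter_chain = FALSE)
  res_inter <- check_restraints(anti, cbind(1, 40), inter_chain = TRUE)
  expect_equal(as.character(res_intra$class), "violated")
  expect_equal(as.character(res_inter$class), "satisfied")
  expect_equal(res_inter$assignment, "inter")

  # self-pair is only measurable across protomers
  self_res <- check_restraints(dimer, cbind(12, 12), inter_chain = TRUE)
  expect_equal(self_res$assignment, "inter")
  expect_equal(self_res$distance, 10, tolerance = 1e-9)

  # unresolved residues are reported, never dropped
  un <- check_restraints(dimer, cbind(c(1, 347), c(30, 349)),
                         inter_chain = TRUE)
  expect_equal(as.character(un$class[2]), "unmappable")
  expect_equal(nrow(un), 2)
})

test_that("the published cross-link table filters to five abundant links", {
  cl <- ire1_xlink_table()
  res <- classify_xlinks(cl, abundance_min = 1.0,
                         condition = "with_peptides")
  got <- paste(res$abundant$lys_a, res$abundant$lys_b, sep = "-")
  expect_setequal(got, c("53-347", "53-349", "53-351", "121-121",
                         "265-351"))
  # the 0.5% link survives only a zero threshold
  res0 <- classify_xlinks(cl, abundance_min = 0,
                          condition = "with_peptides")
  expect_equal(nrow(res0$abundant), 6)
  # a pair with monomer-band signal is never inter-molecular
  mono <- cl
  mono$mean_pct[mono$lys_a == 53 & mono$lys_b == 347 & mono$band == 1] <- 2
  resm <- classify_xlinks(mono, condition = "with_peptides")
  expect_false("53-347" %in% paste(resm$inter$lys_a, resm$inter$lys_b,
                                   sep = "-"))
})

test_that("cross-link classification ignores row order and pair symmetry", {
  cl <- ire1_xlink_table()
  ref <- classify_xlinks(cl, condition = "with_peptides")
  shuffled <- cl[rev(seq_len(nrow(cl))), ]
  expect_equal(classify_xlinks(shuffled, condition = "with_peptides")$abundant,
               ref$abundant)
  flipped <- cl
  flip <- flipped$lys_a == 53
  tmp <- flipped$lys_a[flip]
  flipped$lys_a[flip] <- flipped$lys_b[flip]
  flipped$lys_b[flip] <- tmp
  expect_equal(classify_xlinks(flipped, condition = "with_peptides")$abundant,
               ref$abundant)
})

test_that("interface residues are found by contact distance", {
  far <- helix_dimer(10, offset = 100)
  expect_length(interface_residues(far, "A", "B", cutoff = 5)[["A"]], 0)

  # one designated 4-A contact between otherwise well-separated CA atoms
  close <- structure_model(data.frame(
    chain = rep(c("A", "B"), each = 3), resno = rep(1:3, 2),
    resname = "ALA", elety = "CA", element = "C",
    x = c(0, 20, 40, 24, 100, 140), y = 0, z = 0))
  got <- interface_residues(close, "A", "B", cutoff = 5)
  expect_equal(got[["A"]], 2)
  expect_equal(got[["B"]], 1)

  # cutoff monotonicity
  d <- helix_dimer(20, offset = 9)
  s4 <- interface_residues(d, "A", "B", cutoff = 6)
  s6 <- interface_residues(d, "A", "B", cutoff = 8)
  expect_true(all(s4[["A"]] %in% s6[["A"]]))
  expect_true(all(s4[["B"]] %in% s6[["B"]]))

  expect_error(interface_residues(gen_helix(helix_spec(5)), "A", "B"))
})

test_that("groove geometry admits a 12-mer and rejects a 13-mer", {
  g12 <- peptide_fits_groove(12)
  expect_equal(g12$length, 37.4)
  expect_true(g12$fits)
  g13 <- peptide_fits_groove(13)
  expect_equal(g13$length, 40.8)
  expect_false(g13$fits)
  g2 <- peptide_fits_groove(2)
  expect_equal(g2$length, 3.4)
  expect_true(g2$fits)
  expect_error(peptide_fits_groove(1))
})
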