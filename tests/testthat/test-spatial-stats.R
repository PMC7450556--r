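test_that("pair contact frequency is a symmetric matrix lookup", {
  bt <- bin_table(c(chr1 = 2e6), 5e5) # 4 bins
  m <- matrix(1, 4, 4); m[2, 4] <- 7; m[4, 2] <- 7; diag(m) <- 9
  cm <- contact_matrix(m, bt)
  expect_equal(pair_contact_frequency(cm, 2, 4), 7)
  expect_equal(pair_contact_frequency(cm, 4, 2), 7)
  expect_equal(pair_contact_frequency(cm, 3, 3), 9) # same-bin pair: diagonal
  expect_error(pair_contact_frequency(cm, NA, 2), "unlocated")
  expect_error(pair_contact_frequency(cm, 1, 9), "outside")
})

test_that("intra-chromosome summary counts pairs combinatorially and flags nothing on identical samples", {
  bt <- bin_table(c(chr1 = 3e6), 5e5) # 6 bins
  cm <- contact_matrix(matrix(5, 6, 6), bt) # constant CF everywhere
  ep <- epitope_frame(neo3d:::random_peptides(6),
                      rep(c("positive", "negative"), each = 3),
                      bin = 1:6, bins = bt)
  s <- intra_chromosome_summary(ep, cm, quiet = TRUE)
  expect_equal(nrow(s), 1)
  expect_equal(s$n_pairs_pos, choose(3, 2))
  expect_equal(s$n_pairs_neg, choose(3, 2))
  expect_equal(s$mean_pos, s$mean_neg)
  expect_false(s$significant)
  expect_equal(s$p_value, 1)
})

test_that("chromosomes with too few located epitopes of a label are skipped", {
  bt <- bin_table(c(chr1 = 3e6, chr2 = 3e6), 5e5)
  cm <- simulate_hic(bt, seed = 1)
  ep <- epitope_frame(neo3d:::random_peptides(5),
                      c("positive", "positive", "negative", "negative",
                        "positive"),
                      bin = c(1, 2, 3, 4, 7), bins = bt)
  expect_message(s <- intra_chromosome_summary(ep, cm), "skipping chr2")
  expect_equal(s$chrom, "chr1")
})

test_that("a planted +2-sigma shift in pos-pos contact frequencies is detected", {
  bt <- bin_table(c(chr1 = 1e7), 5e5) # 20 bins
  hits <- sapply(1:30, function(s) {
    withr::with_seed(s, {
      m <- matrix(abs(rnorm(400, mean = 10, sd = 2)), 20, 20)
      m <- (m + t(m)) / 2
      pos_bins <- 1:10
      pp <- t(combn(pos_bins, 2))
      shift <- abs(rnorm(nrow(pp), mean = 14, sd = 2)) # +2 sigma location
      m[pp] <- shift; m[pp[, 2:1]] <- shift
      cm <- contact_matrix(m, bt)
      ep <- epitope_frame(neo3d:::random_peptides(20),
                          rep(c("positive", "negative"), each = 10),
                          bin = 1:20, bins = bt)
      intra_chromosome_summary(ep, cm, quiet = TRUE)$p_value < 0.05
    })
  })
  expect_gte(mean(hits), 0.9)
})

test_that("permutation test is calibrated under random label assignment", {
  bt <- bin_table(c(chr1 = 1e7), 5e5)
  cm <- simulate_hic(bt, checkerboard_strength = 2, seed = 3)
  rates <- sapply(1:60, function(s) {
    withr::with_seed(1000 + s, {
      ep <- epitope_frame(neo3d:::random_peptides(16),
                          sample(rep(c("positive", "negative"), each = 8)),
                          bin = sample(20, 16, replace = TRUE), bins = bt)
    })
    intra_chromosome_summary(ep, cm, test = "permutation", n_perm = 199,
                             seed = s, quiet = TRUE)$p_value < 0.05
  })
  expect_lt(mean(rates), 0.15) # near the nominal 5% level
})

test_that("inter-chromosomal distributions order planted hubs and respect label symmetry", {
  bt <- bin_table(c(chr1 = 3e6, chr2 = 3e6, chr3 = 3e6), 5e5) # 18 bins
  n <- bt$n_bins
  m <- matrix(1, n, n)
  hub <- c(1, 7, 13) # one bin per chromosome hosts positives
  m[hub, hub] <- 20
  diag(m) <- 5
  cm <- contact_matrix(m, bt)
  ep <- epitope_frame(neo3d:::random_peptides(9),
                      rep(c("positive", "negative", "negative"), 3),
                      bin = c(1, 3, 4, 7, 9, 10, 13, 15, 16), bins = bt)
  res <- inter_chromosome_distributions(ep, cm)
  mpp <- res$summary$mean[res$summary$group == "pos-pos"]
  mpn <- res$summary$mean[res$summary$group == "pos-neg"]
  mnn <- res$summary$mean[res$summary$group == "neg-neg"]
  expect_gt(mpp, mpn)
  expect_gte(mpn, mnn)
  # closed-form pair counts minus same-chromosome exclusions
  expect_equal(res$summary$n_pairs[res$summary$group == "pos-pos"],
               choose(3, 2)) # all on different chromosomes
  expect_equal(res$summary$n_pairs[res$summary$group == "neg-neg"],
               choose(6, 2) - 3 * choose(2, 2))
  expect_equal(res$summary$n_pairs[res$summary$group == "pos-neg"],
               3 * 6 - 3 * 2)

  # swapping all labels swaps the pos-pos and neg-neg summaries exactly
  ep_sw <- ep
  ep_sw$label <- ifelse(ep$label == "positive", "negative", "positive")
  res_sw <- inter_chromosome_distributions(ep_sw, cm)
  expect_equal(sort(res$cf[["pos-pos"]]), sort(res_sw$cf[["neg-neg"]]))
  expect_equal(sort(res$cf[["pos-neg"]]), sort(res_sw$cf[["pos-neg"]]))
})

test_that("degenerate all-zero inter-chromosomal matrices yield flat distributions, not stars", {
  bt <- bin_table(c(chr1 = 2e6, chr2 = 2e6), 5e5)
  m <- matrix(0, 8, 8)
  diag(m) <- 1
  cm <- contact_matrix(m, bt)
  ep <- epitope_frame(neo3d:::random_peptides(8),
                      rep(c("positive", "negative"), 4),
                      bin = 1:8, bins = bt)
  res <- inter_chromosome_distributions(ep, cm)
  expect_true(all(res$summary$mean == 0))
  expect_true(all(res$tests$p_value == 1 | is.na(res$tests$p_value)))
  expect_false(any(res$tests$significant, na.rm = TRUE))
})

test_that("same-bin pairs use the diagonal and can be dropped by flag", {
  bt <- bin_table(c(chr1 = 2e6), 5e5)
  m <- matrix(2, 4, 4); diag(m) <- 50
  cm <- contact_matrix(m, bt)
  ep <- epitope_frame(neo3d:::random_peptides(4),
                      c("positive", "positive", "negative", "negative"),
                      bin = c(1, 1, 2, 3), bins = bt)
  kept <- intra_chromosome_summary(ep, cm, quiet = TRUE)
  expect_equal(kept$mean_pos, 50) # the same-bin pair reads the diagonal
  dropped <- intra_chromosome_summary(ep, cm, drop_same_bin = TRUE,
                                      quiet = TRUE)
  expect_equal(dropped$n_pairs_pos, 0)
})
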