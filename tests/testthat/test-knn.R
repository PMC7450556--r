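test_that("model distance averages per-replica Euclidean distances", {
  bt <- bin_table(c(chr1 = 1e6), 5e5) # 2 beads
  one <- manual_ensemble(list(rbind(c(0, 0, 0), c(3, 4, 0))), bt)
  expect_equal(pairwise_model_distance(one, 1, 2), 5)
  expect_equal(pairwise_model_distance(one, 1, 1), 0)

  withr::with_seed(13, {
    coords <- lapply(1:5, function(i) matrix(rnorm(6), 2, 3))
  })
  ens <- manual_ensemble(coords, bt)
  oracle <- mean(sapply(coords, function(x) sqrt(sum((x[1, ] - x[2, ])^2))))
  expect_equal(pairwise_model_distance(ens, 1, 2), oracle, tolerance = 1e-12)
  expect_equal(pairwise_model_distance(ens, 2, 1),
               pairwise_model_distance(ens, 1, 2))
})

test_that("knn_score matches exhaustive sort-and-count on a hand-built chromosome", {
  bt <- bin_table(c(chr1 = 3e6), 5e5) # 6 beads
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                  c(4, 0, 0), c(7, 0, 0), c(11, 0, 0))
  ens <- manual_ensemble(list(coords), bt)
  labels <- c("positive", "negative", "positive", "positive", "negative",
              "negative")
  ep <- epitope_frame(sprintf("PEPTIDE%02d", 1:6), labels, 1:6, bt)
  target <- as.list(ep[1, ])
  for (k in 1:5) {
    got <- knn_score(target, ep, ens, k = k)
    expect_equal(got$knn_score, knn_oracle(target, ep, ens, k))
    expect_equal(got$n_neighbors, k)
  }
  # vote bounds
  all_pos <- ep; all_pos$label <- "positive"
  expect_equal(knn_score(target, all_pos, ens, k = 3)$knn_score, 1)
  all_neg <- ep; all_neg$label <- "negative"
  expect_equal(knn_score(target, all_neg, ens, k = 3)$knn_score, 0)
})

test_that("knn falls back gracefully with few or no same-chromosome neighbours", {
  bt <- bin_table(c(chr1 = 1.5e6, chr2 = 1.5e6), 5e5)
  withr::with_seed(5, {
    ens <- manual_ensemble(list(matrix(rnorm(18), 6, 3)), bt)
  })
  ep <- epitope_frame(sprintf("PEP%d", 1:4),
                      c("positive", "negative", "positive", "positive"),
                      bin = c(1, 2, 4, 5), bins = bt)
  # only one same-chromosome neighbour but k = 10: use all available
  got <- knn_score(as.list(ep[1, ]), ep, ens, k = 10)
  expect_equal(got$n_neighbors, 1L)
  # no same-chromosome neighbours: global positive-rate prior
  lone <- epitope_frame("LONEPEP", "negative", 3, bt)
  pool <- ep[ep$chrom == "chr2", ]
  got2 <- knn_score(as.list(lone[1, ]), pool, ens, k = 10)
  expect_equal(got2$n_neighbors, 0L)
  expect_equal(got2$knn_score, mean(pool$label == "positive"))
  # unlocated target errors with the peptide named
  bad <- lone; bad$bin <- NA
  expect_error(knn_score(as.list(bad[1, ]), ep, ens), "LONEPEP")
})

test_that("distance ties break deterministically by bin then peptide", {
  bt <- bin_table(c(chr1 = 2.5e6), 5e5) # 5 beads
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(1, 0, 0),
                  c(0, 2, 0))
  ens <- manual_ensemble(list(coords), bt)
  # beads 2, 3, 4 all at distance 1 from bead 1
  ep <- epitope_frame(c("TGT", "BBB", "AAA", "CCC", "DDD"),
                      c("positive", "positive", "negative", "negative",
                        "negative"),
                      bin = 1:5, bins = bt)
  got1 <- knn_score(as.list(ep[1, ]), ep, ens, k = 1)
  expect_equal(got1$knn_score, 1) # lowest bin among ties is bead 2 (positive)
  got2 <- knn_score(as.list(ep[1, ]), ep, ens, k = 2)
  expect_equal(got2$knn_score, 0.5) # beads 2 then 3
  # same-bin ties fall back to the peptide string: "AAA" (negative) wins
  ep2 <- ep; ep2$bin[3] <- 2L
  got3 <- knn_score(as.list(ep2[1, ]), ep2, ens, k = 1)
  expect_equal(got3$knn_score, 0)
})

test_that("knn_score is invariant under per-replica rigid motions", {
  bt <- bin_table(c(chr1 = 5e6), 5e5) # 10 beads
  withr::with_seed(23, {
    coords <- lapply(1:4, function(i) matrix(rnorm(30), 10, 3))
    labels <- sample(c("positive", "negative"), 10, replace = TRUE)
  })
  ep <- epitope_frame(sprintf("P%02d", 1:10), labels, 1:10, bt)
  ens <- manual_ensemble(coords, bt)
  th <- c(0.4, 1.1, 2.0, 2.9)
  rots <- lapply(th, function(a)
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3))
  moved <- manual_ensemble(lapply(1:4, function(i)
    coords[[i]] %*% rots[[i]] + matrix(rep(c(i, -i, 2 * i), each = 10), 10, 3)),
    bt)
  for (k in c(1, 3, 5)) {
    a <- knn_score(as.list(ep[2, ]), ep, ens, k = k)
    b <- knn_score(as.list(ep[2, ]), ep, moved, k = k)
    expect_equal(a$knn_score, b$knn_score, tolerance = 1e-9)
  }
})

test_that("baseline rescaling maps to fractional ranks and respects monotone maps", {
  expect_equal(rescale_baseline(c(10, 20, 30)), c(0, 0.5, 1))
  expect_equal(rescale_baseline(c(7, 7, 7)), rep(0.5, 3))
  expect_equal(rescale_baseline(c(1, 3), invert = TRUE), c(1, 0))
  withr::with_seed(3, {
    raw <- rnorm(50)
    expect_equal(rescale_baseline(exp(raw) + 2), rescale_baseline(raw))
    expect_equal(rescale_baseline(raw^3), rescale_baseline(raw))
  })
  # affinity mode: log-transform of nM affinity, lower stays stronger
  aff <- rescale_baseline(c(1, 500, 50000, 1e6), mode = "affinity")
  expect_equal(aff[1], 0)
  expect_equal(aff[3], 1)
  expect_equal(aff[4], 1) # clamped
  expect_true(all(diff(aff) >= 0))
  expect_error(rescale_baseline(c(-1, 2), mode = "affinity"), "positive")
})

test_that("score combination follows baseline minus vote with validated ranges", {
  expect_equal(combine_scores(0.3, 0.8), -0.5)
  expect_equal(combine_scores(0.4, 0), 0.4) # pure baseline fallback
  # monotonicity: higher vote at equal baseline ranks strictly better
  expect_lt(combine_scores(0.5, 0.9), combine_scores(0.5, 0.1))
  # non-decreasing in baseline at fixed vote
  expect_lt(combine_scores(0.2, 0.5), combine_scores(0.9, 0.5))
  expect_error(combine_scores(1.2, 0.5), "\\[0, 1\\]")
  expect_error(combine_scores(0.5, -0.1), "\\[0, 1\\]")
})

test_that("prediction table ranks peptides by combined score", {
  bt <- bin_table(c(chr1 = 5e6), 5e5)
  withr::with_seed(41, {
    ens <- manual_ensemble(lapply(1:3, function(i) matrix(rnorm(30), 10, 3)),
                           bt)
  })
  ep <- epitope_frame(sprintf("Q%02d", 1:10),
                      rep(c("positive", "negative"), each = 5), 1:10, bt)
  baseline <- data.frame(peptide = ep$peptide, allele = ep$allele,
                         raw_score = seq(0, 1, length.out = 10),
                         scale = "unit")
  pred <- predict_immunogenicity(ep, ep, ens, baseline, k = 3)
  expect_equal(nrow(pred), 10)
  expect_equal(pred$combined_score,
               pred$baseline_score - pred$knn_score)
  expect_equal(pred$rank, rank(pred$combined_score, ties.method = "min"))
  expect_error(predict_immunogenicity(ep, ep, ens, baseline[-1, ], k = 3),
               "missing")
})
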