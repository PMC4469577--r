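test_that("initial calls follow the depth-4 / 1-read rules", {
  expect_true(is.na(call_initial_genotype(3L, 0L)))     # depth 3
  expect_equal(call_initial_genotype(4L, 0L), "A")
  expect_equal(call_initial_genotype(0L, 5L), "B")
  expect_equal(call_initial_genotype(3L, 1L), "H")
  m <- call_initial_genotype(matrix(c(4L, 0L), 1), matrix(c(0L, 4L), 1))
  expect_equal(as.vector(m), c("A", "B"))
})

test_that("biallelic extraction ignores off-parent reads", {
  snps <- data.frame(scaffold = "s1", pos = c(100L, 200L), p1 = c("A", "C"),
                     p2 = c("G", "T"))
  tab <- allele_counts(c("s1", "s1"), c(100L, 200L),
                       rbind(c(5, 0, 2, 1), c(0, 3, 2, 4)), "i")
  cc <- extract_biallelic_counts(snps, tab)
  expect_equal(cc$n1, c(5L, 3L))
  expect_equal(cc$n2, c(2L, 4L))
  expect_equal(cc$n_ignored, 3L)  # 1 T at site 1 + 2 G at site 2
})

test_that("similarity score matches the published scoring rule", {
  expect_equal(as.numeric(similarity_score(c("A", "H", "B", "A"),
                                           c("A", "H", "B", "A"))), 1.0)
  expect_equal(as.numeric(similarity_score(c("A", "H", "B", "A"),
                                           c("A", "A", "B", "H"))), 0.75)
  expect_equal(as.numeric(similarity_score(c("A", "B"), c("B", "A"))), 0.0)
  # missing entries leave both numerator and n
  s <- similarity_score(c("A", NA, "B"), c("A", "H", NA))
  expect_equal(as.numeric(s), 1.0)
  expect_equal(attr(s, "n"), 1L)
  expect_true(is.na(similarity_score(c(NA, NA), c("A", "B"))))
})

test_that("block building splits at genotype-pattern flips", {
  v1 <- rep("A", 6); v2 <- rep("B", 6)
  G_same <- matrix(rep(v1, 10), 10, byrow = TRUE)
  expect_equal(build_blocks(G_same), rep(1L, 10))
  # chimeric junction: pattern flip -> boundary exactly at the flip
  G_flip <- rbind(matrix(rep(v1, 7), 7, byrow = TRUE),
                  matrix(rep(v2, 5), 5, byrow = TRUE))
  b <- build_blocks(G_flip)
  expect_equal(length(unique(b)), 2)
  expect_equal(which(diff(b) == 1), 7)
  # threshold 1.0: any disagreement starts a new block
  G_noisy <- rbind(v1, v1, replace(v1, 1, "H"), v1)
  expect_equal(build_blocks(G_noisy, threshold = 1.0), c(1L, 1L, 2L, 3L))
  # per-scaffold ids are globally unique
  bb <- blocks_by_scaffold(rbind(G_same, G_same),
                           rep(c("s1", "s2"), each = 10))
  expect_equal(unique(bb), c(1L, 2L))
})

test_that("window likelihoods match the printed formulas", {
  # error-free limit
  l <- window_likelihoods(10, 10, 0, 0)
  expect_equal(unname(l[1, ]), c(1, 0, 2^-10))
  # defaults, n = n1 = 10: P1P1 = 0.942^10 dominates
  l <- window_likelihoods(10, 10)
  expect_equal(unname(l[1, "P1P1"]), 0.942^10, tolerance = 1e-12)
  expect_equal(unname(which.max(l[1, ])), 1L)  # P1P1 dominates
  expect_equal(unname(l[1, "P1P2"]), ((1 - 0.058 + 0.02) / 2)^10,
               tolerance = 1e-12)
  # balanced reads: heterozygote maximal
  l <- window_likelihoods(5, 10)
  expect_equal(unname(which.max(l[1, ])), 3L)
  expect_error(window_likelihoods(1, 0), "zero")
})

test_that("posterior calls respect priors, symmetry and ties", {
  res <- posterior_genotype(40, 40)
  expect_equal(res$call, "A")
  expect_gt(res$posterior[1, "P1P1"], 0.999)
  expect_equal(posterior_genotype(20, 40)$call, "H")
  expect_equal(posterior_genotype(0, 40)$call, "B")
  expect_equal(rowSums(res$posterior), 1, tolerance = 1e-12)
  # symmetric error model: P(P1P1|n/2) == P(P2P2|n/2)
  sym <- posterior_genotype(20, 40, E1 = 0.05, E2 = 0.05)
  expect_equal(unname(sym$posterior[1, "P1P1"]),
               unname(sym$posterior[1, "P2P2"]), tolerance = 1e-12)
  # engineered exact tie -> missing call
  tie <- posterior_genotype(1, 2, E1 = 0.1, E2 = 0.1,
                            priors = c(P1P1 = 0.5, P2P2 = 0.5, P1P2 = 0))
  expect_true(is.na(tie$call))
})

test_that("posterior agrees with brute-force enumeration (oracle)", {
  for (n in c(1, 3, 6)) for (n1 in 0:n) {
    mine <- posterior_genotype(n1, n)$posterior[1, ]
    oracle <- enumerate_posterior(n1, n, 0.058, 0.02)
    expect_equal(unname(mine), oracle, tolerance = 1e-12)
  }
})

test_that("P(P1P1 | n1) increases strictly in n1 at fixed n", {
  post <- posterior_genotype(0:30, 30)$posterior[, "P1P1"]
  expect_true(all(diff(post) > 0))
})

test_that("sliding windows pool to the depth floor and impute", {
  # one block, 5 sites, one individual with total depth 39: all missing
  n <- matrix(c(8L, 8L, 8L, 8L, 7L), 5, 1)
  n1 <- n
  g <- slide_windows(n1, n, rep(1L, 5), window_min_depth = 40)
  expect_true(all(is.na(g)))
  # depth 40 reached: error-free parent-1 reads -> all A
  n <- matrix(8L, 5, 1); n1 <- n
  g <- slide_windows(n1, n, rep(1L, 5), E1 = 0, E2 = 0.01,
                     window_min_depth = 40)
  expect_true(all(g == "A"))
  # window never crosses a block boundary
  n <- matrix(30L, 4, 1); n1 <- matrix(c(30L, 30L, 0L, 0L), 4, 1)
  g <- slide_windows(n1, n, c(1L, 1L, 2L, 2L), window_min_depth = 40)
  expect_equal(as.vector(g), c("A", "A", "B", "B"))
})

test_that("windowed calls beat initial calls on simulated data", {
  w <- tiny_world()
  cnt <- w$counts
  G0 <- call_initial_genotype(cnt$n1, cnt$n - cnt$n1)
  e0 <- evaluate_concordance(G0, w$truth$genotypes)
  blocks <- blocks_by_scaffold(G0, w$truth$snps$scaffold)
  G1 <- slide_windows(cnt$n1, cnt$n, blocks)
  e1 <- evaluate_concordance(G1, w$truth$genotypes)
  expect_gt(e1$accuracy, e0$accuracy)
  expect_lt(e1$missing_rate, e0$missing_rate)
  # most initial miscalls are homozygote-vs-heterozygote confusions
  expect_gt(e0$miscall_AH + e0$miscall_BH, (1 - e0$accuracy) * 0.9)
})

test_that("concordance metrics and anchor flanks behave", {
  truth <- matrix("A", 2, 4)
  calls <- matrix(c("A", "A", "H", "H", "A", "A", NA, "A"), 2, 4)
  e <- evaluate_concordance(calls, truth)
  expect_equal(e$accuracy, 5 / 7)
  expect_equal(e$missing_rate, 1 / 8)
  expect_equal(e$miscall_AH, 2 / 7)
  expect_equal(evaluate_concordance(truth, truth)$accuracy, 1.0)
  expect_error(evaluate_concordance(calls, matrix(NA_character_, 2, 4)),
               "zero comparable")
  snps <- data.frame(scaffold = "s1", pos = c(1000L, 5000L, 40000L))
  anchors <- data.frame(scaffold = "s1", pos = 2000L, i1 = "H", i2 = "B")
  tm <- anchor_truth_matrix(snps, anchors, c("i1", "i2"), flank_bp = 1e4)
  expect_equal(unname(tm[1:2, 1]), c("H", "H"))
  expect_true(all(is.na(tm[3, ])))
  far <- data.frame(scaffold = "s1", pos = 999999L, i1 = "H", i2 = "B")
  expect_error(anchor_truth_matrix(snps, far, c("i1", "i2")), "no SNP")
})
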