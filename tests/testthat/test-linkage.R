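test_that("kosambi matches its closed form and properties", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.25), 25 * log(3), tolerance = 1e-12)
  expect_equal(kosambi(0.1), 25 * log(1.2 / 0.8), tolerance = 1e-12)
  r <- seq(0, 0.499, by = 0.001)
  d <- kosambi(r)
  expect_true(all(diff(d) > 0))             # strictly increasing
  expect_true(all(diff(diff(d)) > -1e-9))   # convex
  expect_true(all(d >= 100 * r - 1e-9))     # d >= 100 r
  expect_equal(kosambi(1e-4), 100 * 1e-4, tolerance = 1e-4)  # small-r limit
  expect_error(kosambi(0.5), "0.5")
})

test_that("bins partition complete identical genotype columns", {
  G <- rbind(c("A", "H", "B"), c("A", "H", "B"), c("A", "A", "B"),
             c("A", NA, "B"))
  rownames(G) <- paste0("s1:", 1:4)
  bs <- build_bins(G, data.frame(scaffold = "s1", pos = 1:4))
  expect_equal(bs$membership, c(1L, 1L, 2L, NA))
  expect_equal(bs$bins$n_snps, c(2L, 1L))
  expect_equal(bs$bins$start, c(1L, 3L))
  expect_equal(bs$bins$end, c(2L, 3L))
  # pure partition invariant: bin count = distinct complete columns
  w <- tiny_world()
  G <- w$truth$genotypes
  bs <- build_bins(G)
  expect_equal(nrow(bs$representative),
               length(unique(apply(G, 1, paste0, collapse = ""))))
  expect_false(anyNA(bs$membership))  # truth matrix is complete
  expect_error(build_bins(G[0, ]), "empty")
})

test_that("EM recombination fraction agrees with grid-search oracle", {
  set.seed(31)
  w <- tiny_world()
  G <- w$truth$genotypes
  # identical vectors: r = 0 with strong LOD
  g <- G[1, ]
  est <- estimate_rf_f2(g, g)
  expect_equal(est$r, 0, tolerance = 1e-9)
  expect_gt(est$lod, 6)
  # symmetric in argument order
  g2 <- G[nrow(G), ]
  expect_equal(estimate_rf_f2(g, g2)$r, estimate_rf_f2(g2, g)$r,
               tolerance = 1e-9)
  # EM equals grid-search ML on assorted site pairs
  idx <- sample(nrow(G), 12)
  for (i in seq(1, 11, by = 2)) {
    em <- estimate_rf_f2(G[idx[i], ], G[idx[i + 1], ])$r
    expect_lt(abs(em - grid_rf(G[idx[i], ], G[idx[i + 1], ])), 1e-3)
  }
  # independently segregating vectors: r near 0.5, LOD near 0
  rs <- replicate(100, {
    a <- sample(c("A", "H", "H", "B"), 59, replace = TRUE)
    b <- sample(c("A", "H", "H", "B"), 59, replace = TRUE)
    estimate_rf_f2(a, b)$r
  })
  expect_lt(abs(mean(rs) - 0.5), 0.05)
  expect_true(estimate_rf_f2(G[1, 1:5], G[2, 1:5])$low_confidence)
})

test_that("pairwise_rf matches the single-pair estimator", {
  w <- tiny_world()
  R <- build_bins(w$truth$genotypes)$representative[1:15, ]
  rf <- pairwise_rf(R)
  for (i in c(2, 9)) for (j in c(5, 14)) {
    single <- estimate_rf_f2(R[i, ], R[j, ])
    expect_equal(rf$r[i, j], single$r, tolerance = 1e-7)
    expect_equal(rf$lod[i, j], single$lod, tolerance = 1e-6)
  }
  expect_equal(rf$r, t(rf$r), tolerance = 1e-9)
})

test_that("grouping splits chromosomes and flags unplaced bins", {
  w <- tiny_world()
  bs <- build_bins(w$truth$genotypes, w$truth$snps)
  rf <- pairwise_rf(bs$representative)
  groups <- group_bins(rf)
  # two simulated chromosomes -> two groups, consistent with truth
  expect_equal(length(unique(groups)), 2)
  truth_chrom <- bs$bins$chrom
  expect_true(all(tapply(groups, truth_chrom,
                         function(x) length(unique(x)) == 1)))
  # an unlinked singleton becomes its own unplaced group
  R2 <- rbind(bs$representative[1:5, ],
              lone = sample(c("A", "H", "B"), ncol(bs$representative),
                            replace = TRUE, prob = c(1, 2, 1)))
  rf2 <- pairwise_rf(R2)
  rf2$lod[6, ] <- rf2$lod[, 6] <- 0  # force no qualifying edge
  g2 <- group_bins(rf2)
  expect_equal(attr(g2, "unplaced"), 6L)
})

test_that("ordering recovers the exhaustive optimum on small groups", {
  # 3-bin chain from the spec-style example
  r3 <- matrix(c(0, .05, .10, .05, 0, .05, .10, .05, 0), 3)
  ob <- order_bins(list(r = r3, lod = r3 * 0 + 10), 1:3)
  expect_true(identical(ob$order, c(1L, 2L, 3L)) ||
                identical(ob$order, c(3L, 2L, 1L)))
  expect_equal(ob$cm, c(0, kosambi(.05), 2 * kosambi(.05)), tolerance = 1e-9)
  # random 7-bin instances against exhaustive enumeration
  set.seed(17)
  for (rep in 1:5) {
    w <- tiny_world()
    R <- build_bins(w$truth$genotypes)$representative
    pick <- sort(sample(nrow(R), 7))
    rf <- pairwise_rf(R[pick, ])
    ob <- order_bins(rf, seq_len(7))
    ex <- exhaustive_order(rf$r)
    cost <- sum(rf$r[cbind(ob$order[-7], ob$order[-1])])
    expect_equal(cost, ex$cost, tolerance = 1e-9)
  }
  # 2-bin group: trivial order, length = kosambi(r)
  r2 <- matrix(c(0, .2, .2, 0), 2)
  ob2 <- order_bins(list(r = r2), 1:2)
  expect_equal(ob2$cm[2], kosambi(0.2))
})

test_that("map length is invariant under order reversal", {
  w <- tiny_world()
  res <- map_from_genotypes(w$truth$genotypes, w$truth$snps, tiny_cfg(),
                            anchor_labels = w$truth$snps$chrom)
  b <- res$map$bins
  for (g in unique(b$group)) {
    cm <- b$cm[b$group == g]
    expect_true(!is.unsorted(cm))
    expect_equal(max(cm) - min(cm), sum(diff(cm)))  # reversal-invariant total
  }
  # groups carry the anchor labels
  expect_setequal(unique(b$group), unique(w$truth$snps$chrom))
})

test_that("quality matrix concentrates linkage on the diagonal", {
  w <- tiny_world()
  res <- map_from_genotypes(w$truth$genotypes, w$truth$snps, tiny_cfg())
  g <- res$map$bins$group[1]
  ids <- res$map$bins$bin[res$map$bins$group == g]
  idx <- match(ids, rownames(res$bin_set$representative))
  R <- res$bin_set$representative[idx, ]
  rmat <- res$rf$r[idx, idx]
  qm <- quality_matrix(R, rmat)
  expect_equal(unname(diag(qm)), rep(1, nrow(qm)))
  near <- abs(row(qm) - col(qm)) <= 2 & row(qm) != col(qm)
  far <- abs(row(qm) - col(qm)) >= nrow(qm) / 2
  expect_gt(mean(qm[near]), mean(qm[far]))
  # negative control: shuffled order loses the diagonal concentration
  set.seed(5)
  sh <- sample(nrow(qm))
  qs <- quality_matrix(R[sh, ], rmat[sh, sh])
  expect_lt(mean(qs[near]) - mean(qs[far]),
            mean(qm[near]) - mean(qm[far]))
  expect_equal(quality_matrix(R[1, , drop = FALSE],
                              matrix(0, 1, 1))[1, 1], 1.0)
})
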