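test_that("simulated SNP counts are Poisson at the configured density", {
  cfg <- pbm_config(n_chromosomes = 1L, chrom_length_bp = 1e6,
                    chrom_length_cM = 100, scaffolds_per_chrom = 2L)
  counts <- vapply(1:60, function(s) nrow(simulate_parents(cfg, s)$snps),
                   numeric(1))
  expect_true(abs(mean(counts) - 2000) < 3 * sqrt(2000 / 60))
  # variance of the same order as the mean (Poisson-spaced positions)
  expect_gt(var(counts), 2000 * 0.4)
  expect_lt(var(counts), 2000 * 2.5)
})

test_that("parent simulation is deterministic and respects hemi fraction", {
  cfg <- tiny_cfg()
  p1 <- simulate_parents(cfg, 5)
  p2 <- simulate_parents(cfg, 5)
  expect_identical(p1, p2)
  expect_true(all(p1$snps$p1 != p1$snps$p2))
  none <- simulate_parents(tiny_cfg(hemi_fraction = 0), 5)
  expect_false(any(none$snps$hemi))
  expect_error(simulate_parents(pbm_config(chrom_length_bp = 1000), 1),
               "degenerate")
})

test_that("meiosis crossover counts follow Poisson(cM/100)", {
  set.seed(99)
  k <- vapply(1:10000, function(i)
    length(simulate_meiosis(1e6, 150)$xo), numeric(1))
  se <- sqrt(1.5 / 10000)
  expect_lt(abs(mean(k) - 1.5), 3 * se)
  none <- simulate_meiosis(1e6, 0)
  expect_length(none$xo, 0)
  # F2 individual = 2 gametes: 2x Morgans expected crossovers
  k2 <- vapply(1:5000, function(i)
    length(simulate_meiosis(1e6, 100)$xo) +
      length(simulate_meiosis(1e6, 100)$xo), numeric(1))
  expect_lt(abs(mean(k2) - 2.0), 3 * sqrt(2 / 5000))
})

test_that("F2 truth segregates 1:2:1 and is gamete-consistent", {
  w <- tiny_world()
  G <- w$truth$genotypes
  freq <- table(G) / length(G)
  expect_lt(abs(freq[["A"]] - 0.25), 0.03)
  expect_lt(abs(freq[["H"]] - 0.50), 0.04)
  expect_lt(abs(freq[["B"]] - 0.25), 0.03)
  # spot-check genotype consistency with the recorded gametes
  snps <- w$truth$snps
  for (i in c(1L, 7L)) {
    ch <- w$truth$chromosomes$name[1]
    sel <- which(snps$chrom == ch)[1:50]
    g <- w$truth$crossovers[[i]][[ch]]
    o <- (g[[1]]$phase + findInterval(snps$pos[sel], g[[1]]$xo)) %% 2 +
      (g[[2]]$phase + findInterval(snps$pos[sel], g[[2]]$xo)) %% 2
    expect_identical(unname(G[sel, i]), c("A", "H", "B")[o + 1])
  }
})

test_that("read counts match the generative error model", {
  cfg <- tiny_cfg()
  w <- tiny_world()
  cnt <- w$counts
  # conservation: n1 never exceeds depth; deterministic regeneration
  expect_true(all(cnt$n1 <= cnt$n))
  again <- simulate_read_counts(w$truth, cfg$depth_mean, cfg$E1, cfg$E2,
                                seed = 42)
  expect_identical(again$n1, cnt$n1)
  # depth mean within 2% over ~1e5 cells
  expect_lt(abs(mean(cnt$n) - cfg$depth_mean) / cfg$depth_mean, 0.02)
  # heterozygote parent-1 read fraction -> (1 - E1 + E2)/2 = 0.481
  h <- w$truth$genotypes == "H"
  frac <- sum(cnt$n1[h]) / sum(cnt$n[h])
  expect_lt(abs(frac - (1 - cfg$E1 + cfg$E2) / 2), 0.01)
  # error-free, truth A: all reads parent-1
  w0 <- simulate_read_counts(w$truth, 10, 0, 0, seed = 1)
  a <- w$truth$genotypes == "A"
  expect_true(all(w0$n1[a] == w0$n[a]))
})

test_that("allele-table export conserves reads", {
  w <- tiny_world()
  tab <- counts_as_allele_table(w$counts, w$truth, 1L)
  snps <- w$truth$snps
  ord <- order(snps$scaffold, snps$spos)
  tot <- w$counts$n[, 1] + w$counts$contam[, 1]
  expect_equal(rowSums(as.matrix(tab[, c("nA", "nC", "nG", "nT")])),
               unname(tot[ord]))
})

test_that("chimera injection records interior junctions and labels", {
  w <- tiny_world()
  sc <- w$truth$scaffolds
  inj <- inject_misassemblies(sc, 3, seed = 2)
  ch <- inj$chimeras
  expect_equal(nrow(ch), 3)
  lens <- chimera_lengths(ch)
  expect_true(all(ch$junction >= 1 & ch$junction < lens))
  # label rule: paired A/D index -> homoeologous
  expect_equal(classify_pairing("A05", "D05"), "homoeologous")
  expect_equal(classify_pairing("A05", "D06"), "interchromosomal")
  expect_equal(classify_pairing("A05", "A05"), "intrachromosomal")
  expect_equal(ch$class, classify_pairing(ch$chrom1, ch$chrom2))
  # n = 0 leaves the scaffold set unchanged
  same <- inject_misassemblies(sc, 0, seed = 2)
  expect_identical(same$scaffolds, sc)
  expect_error(inject_misassemblies(sc, 100, seed = 2), "exceeds")
})

test_that("centromere hit clusters center on the centromere", {
  chroms <- data.frame(name = c("A01", "D01"), length_bp = 4e6,
                       length_cM = 100, centromere_bp = 2e6)
  h <- simulate_centromere_hits(chroms, 1000, spread_bp = 1e5,
                                background_rate = 0, seed = 9)
  mid <- (h$sstart + h$send) / 2
  for (ch in chroms$name)
    expect_lt(abs(median(mid[h$subject == ch]) - 2e6), 1e4)  # spread/10
  # degenerate spread: every hit at the centromere
  h0 <- simulate_centromere_hits(chroms, 20, spread_bp = 0,
                                 background_rate = 0, seed = 9)
  expect_true(all(h0$sstart == 2e6))
  # per-subgenome asymmetric counts
  ha <- simulate_centromere_hits(chroms, c(A01 = 33, D01 = 270), 1e5, 0, 1)
  expect_equal(sum(ha$subject == "A01"), 33)
  expect_equal(sum(ha$subject == "D01"), 270)
})

test_that("identical config and seed give byte-identical world", {
  a <- simulate_f2(tiny_cfg(), seed = 3)
  b <- simulate_f2(tiny_cfg(), seed = 3)
  expect_identical(a, b)
  c <- simulate_f2(tiny_cfg(), seed = 4)
  expect_false(identical(a$truth$genotypes, c$truth$genotypes))
})
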