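test_that("segment extraction centers on SNPs and skips edges", {
  snps <- data.frame(scaffold = "s1", pos = c(150L, 50L, 500L, 950L))
  seg <- extract_segments(snps, c(s1 = 1000L))
  expect_equal(seg$start, c(50L, 400L))
  expect_equal(seg$end, c(250L, 600L))
  expect_equal(attr(seg, "n_skipped_edge"), 2L)  # pos 50 and 950
  expect_true(all(seg$end - seg$start + 1 == 201))
})

test_that("segment position assignment applies the mapping filters", {
  segs <- data.frame(scaffold = "s1", pos = c(200L, 300L, 400L),
                     start = c(100L, 200L, 300L), end = c(300L, 400L, 500L))
  gp <- data.frame(scaffold = "s1", pos = c(200L, 300L, 400L),
                   bin = c("b1", "b1", "b2"), group = "A01",
                   cm = c(5, 5, 6))
  out <- assign_segment_positions(segs, gp,
                                  unique = c(TRUE, FALSE, TRUE),
                                  match_len = c(201L, 201L, 200L))
  expect_equal(out$pos, 200L)  # multi-mapper and partial match dropped
  expect_equal(out$cm, 5)
  full <- assign_segment_positions(segs, gp)
  expect_equal(nrow(full), 3)
})

test_that("breakpoints require two stable runs with discordant positions", {
  mkseg <- function(groups, cms, bins) {
    n <- length(groups)
    data.frame(scaffold = "sc", pos = seq_len(n) * 100L,
               bin = bins, group = groups, cm = cms)
  }
  # 12 at (A05, 40) then 13 at (D05, 10): one homoeologous breakpoint
  seg <- mkseg(rep(c("A05", "D05"), c(12, 13)), rep(c(40, 10), c(12, 13)),
               rep(c("b1", "b2"), c(12, 13)))
  bp <- detect_misassemblies(seg)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$class, "homoeologous")
  expect_equal(bp$breakpoint, as.integer(floor((1200 + 1300) / 2)))
  # 9 then 30: first run unstable, no breakpoint
  seg <- mkseg(rep(c("A05", "D05"), c(9, 30)), rep(c(40, 10), c(9, 30)),
               rep(c("b1", "b2"), c(9, 30)))
  expect_equal(nrow(detect_misassemblies(seg)), 0)
  # uniform scaffold: none
  seg <- mkseg(rep("A05", 30), rep(40, 30), rep("b1", 30))
  expect_equal(nrow(detect_misassemblies(seg)), 0)
  # small cM jump within tolerance: none; above tolerance: intrachromosomal
  seg <- mkseg(rep("A05", 24), rep(c(40, 43), each = 12),
               rep(c("b1", "b2"), each = 12))
  expect_equal(nrow(detect_misassemblies(seg)), 0)
  seg <- mkseg(rep("A05", 24), rep(c(40, 70), each = 12),
               rep(c("b1", "b2"), each = 12))
  bp <- detect_misassemblies(seg)
  expect_equal(bp$class, "intrachromosomal")
  # scaffold with zero stable runs is reported unanchorable
  seg <- mkseg(rep(c("A05", "D05"), 5), rep(c(40, 10), 5),
               rep(c("b1", "b2"), 5))
  bp <- detect_misassemblies(seg)
  expect_equal(nrow(bp), 0)
  expect_equal(attr(bp, "unanchorable"), "sc")
})

test_that("split/anchor orders by median cM, orients, conserves length", {
  seg <- rbind(
    data.frame(scaffold = "sc1", pos = seq(100, 2000, by = 100),
               bin = "b1", group = "A01", cm = 10),
    data.frame(scaffold = "sc2", pos = seq(100, 2000, by = 100),
               bin = paste0("b", rep(2:5, each = 5)), group = "A01",
               cm = rep(c(46, 44, 42, 40), each = 5)),  # descending cM
    data.frame(scaffold = "sc3", pos = seq(100, 2000, by = 100),
               bin = "b6", group = "A01", cm = 20))
  lens <- c(sc1 = 2100L, sc2 = 2100L, sc3 = 2100L)
  bp <- detect_misassemblies(seg, min_run = 5, cm_jump_tol = 10)
  expect_equal(nrow(bp), 0)
  sa <- split_and_anchor(lens, bp, seg, anchor_min_len = 1000)
  expect_equal(sa$pieces$piece[order(sa$pieces$median_cm)],
               c("sc1", "sc3", "sc2"))
  expect_equal(sa$pieces$orientation[sa$pieces$piece == "sc2"], "-")
  expect_equal(sa$layout$id[sa$layout$type == "W"], c("sc1", "sc3", "sc2"))
  expect_equal(sum(sa$pieces$length), sum(lens))
  # short pieces stay unplaced
  sa2 <- split_and_anchor(lens, bp, seg, anchor_min_len = 5000)
  expect_false(any(sa2$pieces$placed))
})

test_that("chimera splitting keeps pieces single-group and conserves bp", {
  w <- tiny_world()
  cfg <- tiny_cfg()
  res <- map_from_genotypes(w$truth$genotypes, w$truth$snps, cfg,
                            anchor_labels = w$truth$snps$chrom)
  gp_sc <- genetic_positions(res, data.frame(scaffold = w$truth$snps$scaffold,
                                             pos = w$truth$snps$spos))
  inj <- inject_misassemblies(w$truth$scaffolds, 2, seed = 8)
  cst <- chimera_snp_table(w$truth$snps, inj$chimeras)
  key <- paste0(gp_sc$scaffold, ":", gp_sc$pos)
  idx <- match(paste0(cst$src_scaffold, ":", cst$src_pos), key)
  seg <- data.frame(scaffold = cst$scaffold, pos = cst$pos,
                    bin = gp_sc$bin[idx], group = gp_sc$group[idx],
                    cm = gp_sc$cm[idx])
  seg <- seg[!is.na(seg$bin), ]
  bp <- detect_misassemblies(seg)
  expect_equal(sort(unique(bp$scaffold)), sort(inj$chimeras$scaffold))
  lens <- chimera_lengths(inj$chimeras)
  sa <- split_and_anchor(lens, bp, seg, anchor_min_len = 1000)
  expect_equal(sum(sa$pieces$length), sum(lens))
  placed <- sa$pieces[sa$pieces$placed, ]
  expect_true(all(!is.na(placed$group)))
  # every breakpoint lies strictly inside its scaffold
  expect_true(all(bp$breakpoint > 1 & bp$breakpoint < lens[bp$scaffold]))
})

test_that("AGP writer lays out components with gaps", {
  layout <- data.frame(object = "A01", part = NA,
                       type = c("W", "N", "W"),
                       id = c("p1", NA, "p2"),
                       comp_start = c(1L, NA, 1L), comp_end = c(500L, NA, 300L),
                       orientation = c("+", NA, "-"), gap_len = c(NA, 100L, NA))
  f <- withr::local_tempfile(fileext = ".agp")
  write_agp(layout, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##agp-version 2.1")
  p <- strsplit(lines[-1], "\t")
  expect_equal(sapply(p, `[`, 2), c("1", "501", "601"))
  expect_equal(sapply(p, `[`, 3), c("500", "600", "900"))
  expect_equal(p[[3]][9], "-")
})
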