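# Synthetic F2 world: parental genomes, meiosis, low-coverage allele counts
# with parent-specific error rates, chimeric scaffolds, centromere-clustered
# homology hits. Everything downstream is tested against this generator's
# recorded truth.

#' Define the simulated chromosome set
#'
#' Chromosomes are named in allopolyploid A/D style (`A01..`, `D01..`) with the
#' A and D chromosome of equal index forming a homoeologous pair. Each
#' chromosome is cut into equal-length scaffolds and carries one centromere at
#' a fixed relative position.
#'
#' @param cfg A [pbm_config()].
#' @param centromere_rel Relative centromere position along each chromosome.
#' @return list with `chromosomes` (name, length_bp, length_cM, centromere_bp)
#'   and `scaffolds` (scaffold, chrom, start, end; 1-based inclusive source
#'   intervals).
#' @export
sim_chromosomes <- function(cfg = pbm_config(), centromere_rel = 0.45) {
  n <- cfg$n_chromosomes
  stopifnot(n >= 1)
  idx <- rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)]
  sub <- rep(c("A", "D"), length.out = n)
  name <- sprintf("%s%02d", sub, idx)
  len <- rep_len(cfg$chrom_length_bp, n)
  cm <- rep_len(cfg$chrom_length_cM, n)
  chroms <- data.frame(name = name, length_bp = as.integer(len),
                       length_cM = cm,
                       centromere_bp = as.integer(round(centromere_rel * len)),
                       stringsAsFactors = FALSE)
  k <- cfg$scaffolds_per_chrom
  sc <- do.call(rbind, lapply(seq_len(n), function(i) {
    bounds <- round(seq(0, chroms$length_bp[i], length.out = k + 1))
    data.frame(scaffold = sprintf("%s_sc%02d", name[i], seq_len(k)),
               chrom = name[i], start = as.integer(bounds[-(k + 1)] + 1),
               end = as.integer(bounds[-1]), stringsAsFactors = FALSE)
  }))
  list(chromosomes = chroms, scaffolds = sc)
}

#' Simulate parental haplotypes and interspecific SNP positions
#'
#' SNPs are Poisson-spaced (i.i.d. exponential gaps) at the configured density.
#' Parents are homozygous and distinct at every simple SNP; a configurable
#' fraction of sites is flagged hemi: a homoeologous copy contributes a
#' constant 50% stream of a third allele to one parent's read counts.
#'
#' @param cfg A [pbm_config()].
#' @param seed Integer seed.
#' @return list with `snps` (chrom, pos, scaffold, spos, p1, p2, hemi,
#'   hemi_parent, contam), `chromosomes`, `scaffolds`.
#' @export
simulate_parents <- function(cfg = pbm_config(), seed = cfg$seed) {
  set.seed(child_seed(seed, "parents"))
  world <- sim_chromosomes(cfg)
  chroms <- world$chromosomes
  snps <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    L <- chroms$length_bp[i]
    n_exp <- L * cfg$snp_per_bp
    if (n_exp < 10)
      stop("degenerate: expected <10 SNPs on ", chroms$name[i], call. = FALSE)
    gaps <- stats::rexp(ceiling(n_exp * 1.5) + 50, rate = cfg$snp_per_bp)
    pos <- cumsum(gaps)
    pos <- unique(as.integer(ceiling(pos[pos < L])))
    data.frame(chrom = chroms$name[i], pos = pos, stringsAsFactors = FALSE)
  }))
  # parental alleles: draw p1, then a different p2
  m <- nrow(snps)
  p1 <- sample(ALLELES, m, replace = TRUE)
  p2 <- vapply(p1, function(a) sample(setdiff(ALLELES, a), 1), character(1))
  hemi <- runif(m) < cfg$hemi_fraction
  hemi_parent <- ifelse(hemi, sample(1:2, m, replace = TRUE), NA_integer_)
  contam <- rep(NA_character_, m)
  contam[hemi] <- vapply(which(hemi), function(i) {
    sample(setdiff(ALLELES, c(p1[i], p2[i])), 1)
  }, character(1))
  snps$p1 <- p1; snps$p2 <- p2
  snps$hemi <- hemi; snps$hemi_parent <- hemi_parent; snps$contam <- contam
  # scaffold-local coordinates
  sc <- world$scaffolds
  snps$scaffold <- NA_character_; snps$spos <- NA_integer_
  for (j in seq_len(nrow(sc))) {
    sel <- snps$chrom == sc$chrom[j] & snps$pos >= sc$start[j] &
      snps$pos <= sc$end[j]
    snps$scaffold[sel] <- sc$scaffold[j]
    snps$spos[sel] <- snps$pos[sel] - sc$start[j] + 1L
  }
  list(snps = snps, chromosomes = chroms, scaffolds = sc)
}

#' Simulate one meiotic gamete
#'
#' Crossover count is Poisson(length_cM / 100); positions are i.i.d. uniform
#' along the chromosome (no interference); the starting phase is
#' Bernoulli(0.5).
#'
#' @param length_bp Chromosome length in bp.
#' @param length_cM Genetic length in centimorgans.
#' @return list with `xo` (sorted crossover positions, bp) and `phase`
#'   (0 = starts on parent-1 haplotype, 1 = parent-2).
#' @export
simulate_meiosis <- function(length_bp, length_cM) {
  k <- rpois(1, length_cM / 100)
  list(xo = sort(runif(k, 0, length_bp)), phase = sample(0:1, 1))
}

gamete_origin <- function(gamete, pos) {
  (gamete$phase + findInterval(pos, gamete$xo)) %% 2L
}

#' Simulate F2 truth genotypes by meiosis
#'
#' Each individual receives two independent gametes per chromosome; the true
#' genotype at every SNP is A/H/B according to the two parental origins.
#'
#' @param parents Output of [simulate_parents()].
#' @param cfg A [pbm_config()].
#' @param seed Integer seed.
#' @return list of class `f2_truth`: `genotypes` (sites x individuals matrix of
#'   "A"/"H"/"B", rownames `scaffold:spos`), `crossovers` (nested list,
#'   individual -> chromosome -> 2 gametes), `snps`, `chromosomes`,
#'   `scaffolds`.
#' @export
simulate_f2_truth <- function(parents, cfg = pbm_config(), seed = cfg$seed) {
  set.seed(child_seed(seed, "meiosis"))
  snps <- parents$snps
  chroms <- parents$chromosomes
  nind <- cfg$n_individuals
  G <- matrix(NA_character_, nrow(snps), nind)
  rownames(G) <- paste0(snps$scaffold, ":", snps$spos)
  colnames(G) <- sprintf("F2_%03d", seq_len(nind))
  xos <- vector("list", nind)
  for (i in seq_len(nind)) {
    xos[[i]] <- vector("list", nrow(chroms))
    names(xos[[i]]) <- chroms$name
    for (c in seq_len(nrow(chroms))) {
      g1 <- simulate_meiosis(chroms$length_bp[c], chroms$length_cM[c])
      g2 <- simulate_meiosis(chroms$length_bp[c], chroms$length_cM[c])
      xos[[i]][[c]] <- list(g1, g2)
      sel <- snps$chrom == chroms$name[c]
      o <- gamete_origin(g1, snps$pos[sel]) + gamete_origin(g2, snps$pos[sel])
      G[sel, i] <- c("A", "H", "B")[o + 1L]
    }
  }
  structure(list(genotypes = G, crossovers = xos, snps = snps,
                 chromosomes = chroms, scaffolds = parents$scaffolds),
            class = "f2_truth")
}

#' Simulate low-coverage read counts for the F2 population
#'
#' Per-site depth is Poisson(`depth_mean`). Given the true genotype, each read
#' carries the parent-1 allele with probability 1 - E1 (truth A), E1 (truth B),
#' or (1 - E1 + E2) / 2 (truth H); remaining reads carry the parent-2 allele.
#' Hemi sites additionally receive a contaminating homoeolog stream equal in
#' expectation to the locus depth, split 50/50.
#'
#' @param truth An `f2_truth`.
#' @param depth_mean Mean sequencing depth per site.
#' @param E1,E2 Parent-1 / parent-2 per-read error rates.
#' @param seed Integer seed.
#' @return list with integer matrices `n1` (parent-1-allele reads), `n`
#'   (informative depth, = n1 + parent-2 reads), and `contam` (contaminating
#'   reads at hemi sites, 0 elsewhere); all sites x individuals.
#' @export
simulate_read_counts <- function(truth, depth_mean = 5.3, E1 = 0.058,
                                 E2 = 0.02, seed = 1L) {
  stopifnot(depth_mean > 0, E1 >= 0, E1 < 0.5, E2 >= 0, E2 < 0.5)
  set.seed(child_seed(seed, "reads"))
  G <- truth$genotypes
  S <- nrow(G); I <- ncol(G)
  p <- matrix(0, S, I)
  p[G == "A"] <- 1 - E1
  p[G == "B"] <- E1
  p[G == "H"] <- (1 - E1 + E2) / 2
  dep <- matrix(rpois(S * I, depth_mean), S, I)
  n1 <- matrix(rbinom(S * I, as.vector(dep), as.vector(p)), S, I)
  contam <- matrix(0L, S, I)
  hemi <- truth$snps$hemi
  if (any(hemi)) {
    nh <- sum(hemi)
    contam[hemi, ] <- matrix(rpois(nh * I, depth_mean), nh, I)
  }
  dimnames(dep) <- dimnames(n1) <- dimnames(contam) <- dimnames(G)
  list(n1 = n1, n = dep, contam = contam)
}

#' Convert one individual's simulated counts to an allele-count table
#'
#' Places parent-1-allele reads, parent-2-allele reads and any contaminating
#' hemi stream onto their nucleotide columns.
#'
#' @param counts Output of [simulate_read_counts()].
#' @param truth The `f2_truth` the counts came from.
#' @param individual Column index or name.
#' @return An [allele_counts()] table ordered by scaffold and position.
#' @export
counts_as_allele_table <- function(counts, truth, individual) {
  snps <- truth$snps
  n1 <- counts$n1[, individual]; n <- counts$n[, individual]
  ct <- counts$contam[, individual]
  m <- matrix(0L, nrow(snps), 4, dimnames = list(NULL, ALLELES))
  for (a in ALLELES) {
    m[, a] <- (snps$p1 == a) * n1 + (snps$p2 == a) * (n - n1) +
      ifelse(!is.na(snps$contam) & snps$contam == a, ct, 0L)
  }
  ord <- order(snps$scaffold, snps$spos)
  allele_counts(snps$scaffold[ord], snps$spos[ord], m[ord, , drop = FALSE],
                sample_id = as.character(individual))
}

#' Simulate deep parental allele counts
#'
#' Each parent is sequenced at its configured depth; its own allele is read
#' with error rate E1 (parent 1) or E2 (parent 2), errors showing the other
#' parent's allele. At hemi sites the affected parent's coverage is split
#' 50/50 between its own locus and a homoeologous copy carrying the
#' contaminating allele.
#'
#' @param parents Output of [simulate_parents()].
#' @param cfg A [pbm_config()].
#' @param seed Integer seed.
#' @return list of two [allele_counts()] tables.
#' @export
simulate_parent_counts <- function(parents, cfg = pbm_config(),
                                   seed = cfg$seed) {
  set.seed(child_seed(seed, "misc"))
  snps <- parents$snps
  S <- nrow(snps)
  err <- c(cfg$E1, cfg$E2)
  out <- vector("list", 2)
  for (p in 1:2) {
    own <- if (p == 1) snps$p1 else snps$p2
    other <- if (p == 1) snps$p2 else snps$p1
    dep <- rpois(S, cfg$parent_depth_mean[p])
    hemi_here <- snps$hemi & !is.na(snps$hemi_parent) & snps$hemi_parent == p
    locus <- ifelse(hemi_here, rbinom(S, dep, 0.5), dep)
    contam <- dep - locus
    own_reads <- rbinom(S, locus, 1 - err[p])
    err_reads <- locus - own_reads
    m <- matrix(0L, S, 4, dimnames = list(NULL, ALLELES))
    for (a in ALLELES) {
      m[, a] <- (own == a) * own_reads + (other == a) * err_reads +
        ifelse(!is.na(snps$contam) & snps$contam == a & hemi_here, contam, 0L)
    }
    ord <- order(snps$scaffold, snps$spos)
    out[[p]] <- allele_counts(snps$scaffold[ord], snps$spos[ord],
                              m[ord, , drop = FALSE],
                              sample_id = paste0("parent", p))
  }
  out
}

#' Inject chimeric scaffolds
#'
#' Each chimera concatenates the left part of one scaffold with the right part
#' of a second scaffold drawn from a different genomic location. The junction
#' offset (scaffold-local, strictly interior) and a classification label are
#' recorded as truth: homoeologous when the two source chromosomes are the
#' A/D pair of the same index, interchromosomal for other cross-chromosome
#' pairs, intrachromosomal for same-chromosome pairs.
#'
#' @param scaffolds Scaffold table from [sim_chromosomes()].
#' @param n_chimeras Number of chimeras to inject.
#' @param seed Integer seed.
#' @return list with `scaffolds` (untouched scaffolds), `chimeras`
#'   (scaffold, chrom1, start1, end1, chrom2, start2, end2, junction, class).
#' @export
inject_misassemblies <- function(scaffolds, n_chimeras, seed = 1L) {
  set.seed(child_seed(seed, "chimera"))
  if (n_chimeras == 0)
    return(list(scaffolds = scaffolds, chimeras = empty_chimeras()))
  if (2 * n_chimeras > nrow(scaffolds))
    stop("n_chimeras exceeds available scaffolds", call. = FALSE)
  if (length(unique(scaffolds$chrom)) < 2)
    stop("need scaffolds from >=2 chromosomes", call. = FALSE)
  picked <- sample(nrow(scaffolds), 2 * n_chimeras)
  a <- picked[seq_len(n_chimeras)]
  b <- picked[n_chimeras + seq_len(n_chimeras)]
  # ensure each pair spans two distinct locations (re-pair same-scaffold draws)
  ch <- data.frame(
    scaffold = sprintf("chimera_%02d", seq_len(n_chimeras)),
    chrom1 = scaffolds$chrom[a], start1 = scaffolds$start[a],
    end1 = scaffolds$end[a],
    chrom2 = scaffolds$chrom[b], start2 = scaffolds$start[b],
    end2 = scaffolds$end[b], stringsAsFactors = FALSE)
  len1 <- ch$end1 - ch$start1 + 1L
  # keep the left part of scaffold 1 (about half), splice on right part of 2
  cut1 <- as.integer(round(len1 * runif(n_chimeras, 0.35, 0.65)))
  ch$end1 <- ch$start1 + cut1 - 1L
  len2 <- ch$end2 - ch$start2 + 1L
  cut2 <- as.integer(round(len2 * runif(n_chimeras, 0.35, 0.65)))
  ch$start2 <- ch$start2 + cut2
  ch$junction <- cut1  # junction between local offset cut1 and cut1+1
  ch$class <- classify_pairing(ch$chrom1, ch$chrom2)
  keep <- scaffolds[-picked, , drop = FALSE]
  list(scaffolds = keep, chimeras = ch)
}

empty_chimeras <- function() {
  data.frame(scaffold = character(), chrom1 = character(), start1 = integer(),
             end1 = integer(), chrom2 = character(), start2 = integer(),
             end2 = integer(), junction = integer(), class = character(),
             stringsAsFactors = FALSE)
}

#' Classify a chromosome pairing (A/D homoeolog convention)
#'
#' @param g1,g2 Chromosome/group names like "A05", "D05".
#' @return "homoeologous", "interchromosomal" or "intrachromosomal".
#' @export
classify_pairing <- function(g1, g2) {
  same <- g1 == g2
  idx1 <- sub("^[AD]", "", g1); idx2 <- sub("^[AD]", "", g2)
  sub1 <- substr(g1, 1, 1); sub2 <- substr(g2, 1, 1)
  ifelse(same, "intrachromosomal",
         ifelse(idx1 == idx2 & sub1 != sub2, "homoeologous",
                "interchromosomal"))
}

#' Simulate centromere-clustered homology hits
#'
#' True hits are Normal(centromere, spread) truncated to the chromosome, with
#' identities >= 80% and e-values <= 1e-20; background hits are uniform along
#' the chromosome with mixed identities/e-values straddling the filter
#' thresholds.
#'
#' @param chromosomes Chromosome table from [sim_chromosomes()].
#' @param n_hits_per_chrom True hit count per chromosome; a named vector
#'   (names = chromosome) or a scalar.
#' @param spread_bp SD of the true hit cluster.
#' @param background_rate Expected background hits per chromosome.
#' @param seed Integer seed.
#' @param query Query LTR label(s) to cycle through.
#' @return Hit data.frame in the shape of [read_hit_table()] output.
#' @export
simulate_centromere_hits <- function(chromosomes, n_hits_per_chrom = 200,
                                     spread_bp = 1e5, background_rate = 0,
                                     seed = 1L, query = c("CR1_LTR", "CR3_LTR")) {
  stopifnot(spread_bp >= 0)
  set.seed(child_seed(seed, "hits"))
  rows <- lapply(seq_len(nrow(chromosomes)), function(i) {
    nm <- chromosomes$name[i]; L <- chromosomes$length_bp[i]
    cen <- chromosomes$centromere_bp[i]
    ntrue <- if (!is.null(names(n_hits_per_chrom)))
      n_hits_per_chrom[[nm]] else n_hits_per_chrom[[1]]
    pos <- numeric(0)
    while (length(pos) < ntrue) {
      cand <- rnorm(2 * ntrue + 10, cen, max(spread_bp, .Machine$double.eps))
      pos <- c(pos, cand[cand >= 1 & cand <= L])
    }
    pos <- as.integer(round(pos[seq_len(ntrue)]))
    nbg <- if (background_rate > 0) rpois(1, background_rate) else 0L
    bpos <- as.integer(ceiling(runif(nbg, 0, L)))
    ident <- c(runif(ntrue, 80, 100), runif(nbg, 50, 100))
    ev <- c(10^runif(ntrue, -60, -21), 10^runif(nbg, -30, -1))
    allpos <- c(pos, bpos)
    n <- length(allpos)
    if (n == 0) return(NULL)
    data.frame(query = rep_len(query, n), subject = nm,
               identity = round(ident, 2), length = 100L,
               mismatches = 0L, gapopens = 0L, qstart = 1L, qend = 100L,
               sstart = allpos, send = allpos + 99L,
               evalue = signif(ev, 3), bitscore = 180,
               strand = "+", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-call synthetic F2 world
#'
#' Chains [simulate_parents()], [simulate_f2_truth()] and
#' [simulate_read_counts()] under one master seed (stage seeds are fixed
#' offsets of it, so the whole world is reproducible byte for byte).
#'
#' @param cfg A [pbm_config()].
#' @param seed Master seed (defaults to `cfg$seed`).
#' @return list with `parents`, `truth`, `counts`.
#' @export
simulate_f2 <- function(cfg = pbm_config(), seed = cfg$seed) {
  parents <- simulate_parents(cfg, seed)
  truth <- simulate_f2_truth(parents, cfg, seed)
  counts <- simulate_read_counts(truth, cfg$depth_mean, cfg$E1, cfg$E2, seed)
  list(parents = parents, truth = truth, counts = counts)
}

#' SNP coordinates on injected chimeric scaffolds
#'
#' Lifts the simulated SNPs falling inside a chimera's two source fragments
#' onto the chimera's local coordinate system (fragment 2 appended after the
#' junction), so genotype/segment analyses can be run on the chimeras exactly
#' as on honest scaffolds.
#'
#' @param snps SNP table from [simulate_parents()].
#' @param chimeras Chimera table from [inject_misassemblies()].
#' @return data.frame `scaffold` (chimera id), `pos` (chimera-local),
#'   `src_scaffold`, `src_pos` (source scaffold-local), `src_chrom`,
#'   `side` (1 left of junction, 2 right).
#' @export
chimera_snp_table <- function(snps, chimeras) {
  rows <- lapply(seq_len(nrow(chimeras)), function(i) {
    ch <- chimeras[i, ]
    s1 <- snps[snps$chrom == ch$chrom1 & snps$pos >= ch$start1 &
                 snps$pos <= ch$end1, , drop = FALSE]
    s2 <- snps[snps$chrom == ch$chrom2 & snps$pos >= ch$start2 &
                 snps$pos <= ch$end2, , drop = FALSE]
    data.frame(scaffold = ch$scaffold,
               pos = c(s1$pos - ch$start1 + 1L,
                       ch$junction + (s2$pos - ch$start2 + 1L)),
               src_scaffold = c(s1$scaffold, s2$scaffold),
               src_pos = c(s1$spos, s2$spos),
               src_chrom = c(s1$chrom, s2$chrom),
               side = rep(1:2, c(nrow(s1), nrow(s2))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Length of each injected chimera
#'
#' @param chimeras Chimera table from [inject_misassemblies()].
#' @return Named integer vector of chimera lengths.
#' @export
chimera_lengths <- function(chimeras) {
  setNames(chimeras$junction + (chimeras$end2 - chimeras$start2 + 1L),
           chimeras$scaffold)
}
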