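# Two-step genotyper. Step one: per-site initial calls (depth >= 4, >= 1 read
# per allele) and similarity-score partitioning of each scaffold's SNPs into
# blocks (threshold 0.7). Step two: a depth-adaptive sliding window pools
# reads over consecutive same-block sites until >= 40 reads, then makes a
# Bayesian call under binomial likelihoods with parent-specific error rates
# E1/E2 and F2 priors 1:2:1.

#' Initial per-site genotype calls
#'
#' Counts of reads carrying the parent-1 and parent-2 allele are compared
#' against the initial thresholds: informative depth (n1 + n2) below
#' `min_depth` gives missing; otherwise only-parent-1 reads give A,
#' only-parent-2 give B, and at least one read of each gives H. Reads carrying
#' neither parental allele are not informative and must be excluded upstream
#' (see [extract_biallelic_counts()]).
#'
#' @param n1,n2 Integer vectors/matrices of parent-1 / parent-2 allele reads.
#' @param min_depth Depth floor (default 4).
#' @param min_allele_reads Reads needed to count an allele as observed
#'   (default 1).
#' @return Character vector/matrix in `c("A","B","H", NA)`.
#' @export
call_initial_genotype <- function(n1, n2, min_depth = 4, min_allele_reads = 1) {
  g <- ifelse(n1 + n2 < min_depth, NA_character_,
         ifelse(n1 >= min_allele_reads & n2 >= min_allele_reads, "H",
           ifelse(n1 >= min_allele_reads & n2 < min_allele_reads, "A",
             ifelse(n2 >= min_allele_reads, "B", NA_character_))))
  if (is.matrix(n1)) {
    g <- matrix(g, nrow(n1), ncol(n1))
    dimnames(g) <- dimnames(n1)
  }
  g
}

#' Extract parental-allele read counts from an allele-count table
#'
#' Aligns an individual's allele counts to a simple-SNP table and splits each
#' site's reads into parent-1-allele, parent-2-allele, and ignored (neither
#' allele) streams.
#'
#' @param snps Simple-SNP table (`scaffold, pos, p1, p2`).
#' @param tab An [allele_counts()] table for one individual.
#' @return list with vectors `n1`, `n2` (aligned to `snps`; 0 where the site
#'   is absent from `tab`) and scalar `n_ignored`.
#' @export
extract_biallelic_counts <- function(snps, tab) {
  key_s <- paste0(snps$scaffold, ":", snps$pos)
  key_t <- paste0(tab$scaffold, ":", tab$pos)
  idx <- match(key_s, key_t)
  m <- as.matrix(tab[, c("nA", "nC", "nG", "nT")])
  colnames(m) <- ALLELES
  pick <- function(allele) {
    v <- m[cbind(idx, match(allele, ALLELES))]
    v[is.na(v)] <- 0L
    as.integer(v)
  }
  n1 <- pick(snps$p1); n2 <- pick(snps$p2)
  tot <- rowSums(m)[idx]; tot[is.na(tot)] <- 0
  list(n1 = n1, n2 = n2, n_ignored = as.integer(sum(tot - n1 - n2)))
}

#' Similarity score between two sites' genotype vectors
#'
#' Per individual: s = 1 when the two genotypes are identical, 0.5 when they
#' differ and one is H, 0 when they differ and neither is H. Individuals
#' missing either genotype are excluded from both the numerator and the
#' denominator n.
#'
#' @param gz,gj Character vectors over the same individuals
#'   (`c("A","B","H", NA)`).
#' @return Score in `[0, 1]` with attribute `n` (jointly scored individuals);
#'   `NA` (n = 0) when no individual is jointly scored.
#' @export
similarity_score <- function(gz, gj) {
  stopifnot(length(gz) == length(gj))
  ok <- !is.na(gz) & !is.na(gj)
  n <- sum(ok)
  if (n == 0) return(structure(NA_real_, n = 0L))
  a <- gz[ok]; b <- gj[ok]
  s <- ifelse(a == b, 1, ifelse(a == "H" | b == "H", 0.5, 0))
  structure(sum(s) / n, n = n)
}

# per-individual score of a site vector against consensus counts (3 x I matrix
# of A/H/B tallies); used by build_blocks
consensus_call <- function(cnt) {
  # deterministic tie-break: A before H before B
  tot <- colSums(cnt)
  idx <- apply(cnt, 2, which.max)
  out <- c("A", "H", "B")[idx]
  out[tot == 0] <- NA_character_
  out
}

#' Partition a scaffold's SNP sites into similarity blocks
#'
#' Greedy left-to-right agglomeration in position order: a site joins the
#' current block when its similarity score against the block's running
#' consensus (per-individual majority, missing-aware) is at least `threshold`
#' (default 0.7); otherwise it starts a new block. Blocks are therefore
#' contiguous in position. An undefined score (no jointly scored individual)
#' also starts a new block.
#'
#' @param G Character matrix (sites x individuals) of initial genotype calls,
#'   rows ordered by position within one scaffold.
#' @param threshold Minimum similarity score (default 0.7).
#' @return Integer vector of block ids (1-based, increasing along the
#'   scaffold).
#' @export
build_blocks <- function(G, threshold = 0.7) {
  S <- nrow(G)
  if (S == 0) return(integer(0))
  I <- ncol(G)
  blocks <- integer(S)
  lv <- c("A", "H", "B")
  cnt <- matrix(0L, 3, I)
  add_site <- function(cnt, g) {
    for (k in 1:3) cnt[k, ] <- cnt[k, ] + (!is.na(g) & g == lv[k])
    cnt
  }
  blocks[1] <- 1L
  cnt <- add_site(cnt, G[1, ])
  if (S > 1) for (s in 2:S) {
    sc <- similarity_score(G[s, ], consensus_call(cnt))
    if (!is.na(sc) && sc >= threshold) {
      blocks[s] <- blocks[s - 1]
      cnt <- add_site(cnt, G[s, ])
    } else {
      blocks[s] <- blocks[s - 1] + 1L
      cnt <- add_site(matrix(0L, 3, I), G[s, ])
    }
  }
  blocks
}

#' Blocks across a multi-scaffold site table
#'
#' Runs [build_blocks()] per scaffold and returns globally unique block ids.
#'
#' @param G Initial genotype matrix (sites x individuals).
#' @param scaffold Character vector of scaffold ids per site (sites ordered by
#'   position within scaffold).
#' @param threshold Similarity threshold.
#' @return Integer block ids per site.
#' @export
blocks_by_scaffold <- function(G, scaffold, threshold = 0.7) {
  out <- integer(nrow(G))
  base <- 0L
  for (sc in unique(scaffold)) {
    sel <- which(scaffold == sc)
    b <- build_blocks(G[sel, , drop = FALSE], threshold)
    out[sel] <- b + base
    base <- base + max(b)
  }
  out
}

window_loglik <- function(n1, n, E1, E2) {
  if (any(n == 0)) stop("window depth is zero", call. = FALSE)
  stopifnot(all(n1 >= 0), all(n1 <= n))
  xlog <- function(k, p) ifelse(k == 0, 0, k * log(p))
  lc <- lchoose(n, n1)
  cbind(P1P1 = lc + xlog(n1, 1 - E1) + xlog(n - n1, E2),
        P2P2 = lc + xlog(n1, E1) + xlog(n - n1, 1 - E2),
        P1P2 = lc + xlog(n1, (1 - E1 + E2) / 2) +
          xlog(n - n1, (1 + E1 - E2) / 2))
}

#' Window genotype likelihoods
#'
#' Binomial probabilities of observing `n1` parent-1-allele reads out of `n`
#' window reads under the three F2 genotypes, with parent-specific error
#' rates: P(n1|P1P1) = C(n,n1) (1-E1)^n1 E2^(n-n1); P(n1|P2P2) =
#' C(n,n1) E1^n1 (1-E2)^(n-n1); P(n1|P1P2) = C(n,n1) p^n1 (1-p)^(n-n1) with
#' p = (1-E1+E2)/2 (the heterozygote per-read probability carries the 1/2
#' normalization). Computation is in log space.
#'
#' @param n1 Parent-1-allele read count(s).
#' @param n Total window reads (scalar or same length as `n1`).
#' @param E1,E2 Error rates.
#' @return Matrix (length(n1) x 3) of likelihoods, columns P1P1, P2P2, P1P2.
#' @export
window_likelihoods <- function(n1, n, E1 = 0.058, E2 = 0.02) {
  exp(window_loglik(n1, rep_len(n, length(n1)), E1, E2))
}

#' Posterior window genotype
#'
#' Prior-weighted window likelihoods normalized to sum one; the call is the
#' maximum-posterior genotype (A = P1P1, B = P2P2, H = P1P2), with exact ties
#' returned as missing.
#'
#' @param n1,n Window read counts (vectors allowed).
#' @param E1,E2 Error rates.
#' @param priors F2 priors, default `c(P1P1 = 0.25, P2P2 = 0.25, P1P2 = 0.5)`.
#' @return list with `call` (character vector in `c("A","B","H", NA)`) and
#'   `posterior` (matrix, rows summing to 1).
#' @export
posterior_genotype <- function(n1, n, E1 = 0.058, E2 = 0.02,
                               priors = c(P1P1 = 0.25, P2P2 = 0.25, P1P2 = 0.5)) {
  ll <- window_loglik(n1, rep_len(n, length(n1)), E1, E2)
  lp <- sweep(ll, 2, log(priors), `+`)
  lp <- lp - apply(lp, 1, max)
  w <- exp(lp)
  post <- w / rowSums(w)
  stopifnot(all(is.finite(post)))
  top <- apply(post, 1, max)
  tie <- rowSums(post == top) > 1
  idx <- apply(post, 1, which.max)
  call <- c("A", "B", "H")[idx]
  call[tie] <- NA_character_
  list(call = call, posterior = post)
}

#' Sliding-window Bayesian genotype imputation
#'
#' For every site and individual, a window grows symmetrically over
#' consecutive same-block sites (preferring the nearer site in index distance,
#' left on ties) until the pooled informative depth reaches
#' `window_min_depth` (default 40) or the block is exhausted. An exhausted
#' block below the floor yields missing; otherwise [posterior_genotype()] on
#' the pooled counts gives the site's imputed call.
#'
#' @param n1,n Integer matrices (sites x individuals) of parent-1 reads and
#'   informative depth.
#' @param blocks Integer block ids per site (from [blocks_by_scaffold()]).
#' @param E1,E2 Error rates.
#' @param window_min_depth Depth floor (default 40).
#' @param priors F2 priors.
#' @return Character matrix of imputed genotypes.
#' @export
slide_windows <- function(n1, n, blocks, E1 = 0.058, E2 = 0.02,
                          window_min_depth = 40,
                          priors = c(P1P1 = 0.25, P2P2 = 0.25, P1P2 = 0.5)) {
  stopifnot(nrow(n1) == length(blocks), all(dim(n1) == dim(n)))
  pooled <- pool_window_counts(n1, n, as.integer(blocks),
                               as.integer(window_min_depth))
  pn1 <- pooled$n1; pn <- pooled$n
  out <- matrix(NA_character_, nrow(n1), ncol(n1), dimnames = dimnames(n1))
  ok <- pn >= window_min_depth
  if (any(ok)) {
    # dedupe (n1, n) pairs: the posterior only depends on the pooled counts
    key <- paste0(pn1[ok], "/", pn[ok])
    uk <- !duplicated(key)
    res <- posterior_genotype(pn1[ok][uk], pn[ok][uk], E1, E2, priors)
    out[ok] <- res$call[match(key, key[uk])]
  }
  out
}

#' Concordance of calls against reference genotypes
#'
#' @param calls Character matrix of genotype calls.
#' @param truth Character matrix of reference genotypes (NA = not scored);
#'   same shape as `calls`.
#' @return list: `accuracy` (concordant / compared over jointly non-missing
#'   cells), `missing_rate` (missing calls over truth-scored cells),
#'   `miscall_AH` and `miscall_BH` (directionally pooled A<->H and B<->H
#'   discordance rates over compared cells), `n_compared`.
#' @export
evaluate_concordance <- function(calls, truth) {
  stopifnot(all(dim(calls) == dim(truth)))
  scored <- !is.na(truth)
  if (!any(scored)) stop("zero comparable sites", call. = FALSE)
  missing_rate <- sum(is.na(calls) & scored) / sum(scored)
  both <- scored & !is.na(calls)
  n <- sum(both)
  if (n == 0) stop("zero comparable sites", call. = FALSE)
  acc <- sum(calls[both] == truth[both]) / n
  pair <- paste0(truth[both], calls[both])
  list(accuracy = acc, missing_rate = missing_rate,
       miscall_AH = sum(pair %in% c("AH", "HA")) / n,
       miscall_BH = sum(pair %in% c("BH", "HB")) / n,
       n_compared = n)
}

#' Build a truth matrix from anchor markers
#'
#' Anchor markers (e.g. SSRs) with known genotypes donate their genotype to
#' every SNP within a flank window of their position on the same scaffold,
#' mirroring anchor-based validation of sequence genotypes.
#'
#' @param snps Site table (`scaffold, pos`), rows aligned to the call matrix.
#' @param anchors data.frame `scaffold, pos` plus one column per individual.
#' @param individuals Individual (column) names of the call matrix.
#' @param flank_bp Flank half-width (default 10 kb).
#' @return Character matrix (sites x individuals), NA outside flanks.
#' @export
anchor_truth_matrix <- function(snps, anchors, individuals, flank_bp = 1e4) {
  out <- matrix(NA_character_, nrow(snps), length(individuals),
                dimnames = list(paste0(snps$scaffold, ":", snps$pos),
                                individuals))
  for (i in seq_len(nrow(anchors))) {
    sel <- snps$scaffold == anchors$scaffold[i] &
      abs(snps$pos - anchors$pos[i]) <= flank_bp
    if (any(sel))
      out[sel, ] <- matrix(unlist(anchors[i, individuals]), sum(sel),
                           length(individuals), byrow = TRUE)
  }
  if (!any(!is.na(out))) stop("no SNP falls in any anchor flank", call. = FALSE)
  out
}
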