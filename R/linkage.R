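# Bin-map construction: collapse imputed genotypes into recombination bins,
# estimate pairwise recombination fractions by EM for an F2 intercross,
# group by single linkage under r < 0.4 & LOD >= 6, order by PCoA-seeded
# 2-opt, and scale distances with the Kosambi function.

#' Kosambi mapping function
#'
#' d = 25 ln((1 + 2r) / (1 - 2r)) centimorgans. Strictly increasing and convex
#' on `[0, 0.5)` with d >= 100 r and small-r limit d ~ 100 r.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in cM.
#' @examples
#' kosambi(0.25)  # 25 * log(3)
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)", call. = FALSE)
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Collapse sites into recombination bins
#'
#' A recombination bin is a maximal class of SNP sites with identical,
#' complete genotype vectors across the population (no recombination between
#' any pair of members and no missing call). Sites retaining a missing call
#' are set aside rather than binned.
#'
#' @param G Character genotype matrix (sites x individuals).
#' @param sites Optional site table (`scaffold, pos`, and `chrom` if known),
#'   rows aligned to `G`.
#' @return list of class `bin_set`: `membership` (bin id per site, NA for
#'   set-aside sites), `representative` (bins x individuals matrix), `bins`
#'   (id, n_snps, first scaffold/pos span when `sites` given).
#' @export
build_bins <- function(G, sites = NULL) {
  if (!nrow(G)) stop("empty genotype matrix", call. = FALSE)
  complete <- rowSums(is.na(G)) == 0
  membership <- rep(NA_integer_, nrow(G))
  key <- rep(NA_character_, nrow(G))
  key[complete] <- apply(G[complete, , drop = FALSE], 1, paste0, collapse = "")
  first <- which(complete & !duplicated(key) & !is.na(key))
  ids <- seq_along(first)
  membership[complete] <- match(key[complete], key[first])
  rep_mat <- G[first, , drop = FALSE]
  rownames(rep_mat) <- sprintf("bin%04d", ids)
  bins <- data.frame(bin = rownames(rep_mat),
                     n_snps = as.integer(tabulate(membership, length(ids))),
                     stringsAsFactors = FALSE)
  if (!is.null(sites)) {
    bins$scaffold <- sites$scaffold[first]
    agg_min <- tapply(sites$pos[complete], membership[complete], min)
    agg_max <- tapply(sites$pos[complete], membership[complete], max)
    bins$start <- as.integer(agg_min[as.character(ids)])
    bins$end <- as.integer(agg_max[as.character(ids)])
    if (!is.null(sites$chrom)) bins$chrom <- sites$chrom[first]
  }
  structure(list(membership = membership, representative = rep_mat,
                 bins = bins), class = "bin_set")
}

# encode A/H/B as 0/1/2 indicator matrices
geno_indicators <- function(R) {
  list(I0 = (!is.na(R) & R == "A") + 0,
       I1 = (!is.na(R) & R == "H") + 0,
       I2 = (!is.na(R) & R == "B") + 0)
}

# EM for F2 recombination fraction; inputs are the 9 genotype-pair class
# counts (vectors over pairs), phase of the double heterozygote handled as a
# coupling/repulsion mixture. Deterministic init r0 = 0.25.
em_rf <- function(n00, n01, n02, n10, n11, n12, n20, n21, n22,
                  tol = 1e-8, max_iter = 200) {
  N <- n00 + n01 + n02 + n10 + n11 + n12 + n20 + n21 + n22
  Rk <- n01 + n10 + n12 + n21 + 2 * (n02 + n20)
  r <- rep(0.25, length(N))
  for (it in seq_len(max_iter)) {
    w <- 2 * r^2 / ((1 - r)^2 + r^2)     # E[rec gametes | double het]
    rn <- ifelse(N > 0, (Rk + n11 * w) / (2 * N), 0.5)
    rn <- pmin(pmax(rn, 0), 0.5)
    if (max(abs(rn - r)) < tol) { r <- rn; break }
    r <- rn
  }
  r
}

f2_loglik <- function(r, n00, n01, n02, n10, n11, n12, n20, n21, n22) {
  xlog <- function(k, p) ifelse(k == 0, 0, k * log(p))
  fpar <- ((1 - r) / 2)^2; frec <- (r / 2)^2; fmix <- r * (1 - r) / 2
  fdh <- ((1 - r)^2 + r^2) / 2
  xlog(n00 + n22, fpar) + xlog(n02 + n20, frec) +
    xlog(n01 + n10 + n12 + n21, fmix) + xlog(n11, fdh)
}

#' Recombination fraction between two loci in an F2
#'
#' Maximum-likelihood estimate for two codominant loci via EM over the nine
#' genotype-pair classes (the coupling/repulsion phase of double
#' heterozygotes is a mixture handled in the E step). LOD is the base-10 log
#' likelihood ratio of the estimate against independence (r = 0.5).
#'
#' @param g1,g2 Genotype vectors (`c("A","B","H", NA)`) over the same
#'   individuals.
#' @param min_informative Jointly scored individuals below which the estimate
#'   is flagged low-confidence (default 10).
#' @return list `r`, `lod`, `n` (jointly scored), `low_confidence`.
#' @export
estimate_rf_f2 <- function(g1, g2, min_informative = 10) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  a <- match(g1[ok], c("A", "H", "B")) - 1L
  b <- match(g2[ok], c("A", "H", "B")) - 1L
  cnt <- table(factor(a, 0:2), factor(b, 0:2))
  n <- as.vector(cnt)  # column-major: (0,0),(1,0),(2,0),(0,1),...
  r <- em_rf(n[1], n[4], n[7], n[2], n[5], n[8], n[3], n[6], n[9])
  ll <- f2_loglik(r, n[1], n[4], n[7], n[2], n[5], n[8], n[3], n[6], n[9])
  ll0 <- f2_loglik(0.5, n[1], n[4], n[7], n[2], n[5], n[8], n[3], n[6], n[9])
  list(r = r, lod = max((ll - ll0) / log(10), 0), n = sum(ok),
       low_confidence = sum(ok) < min_informative)
}

#' All pairwise recombination fractions between bins
#'
#' Vectorized EM across every bin pair (class counts via indicator-matrix
#' cross products), returning symmetric r and LOD matrices.
#'
#' @param R Representative genotype matrix (bins x individuals).
#' @return list with matrices `r` and `lod`.
#' @export
pairwise_rf <- function(R) {
  I <- geno_indicators(R)
  cnt <- list()
  for (u in 0:2) for (v in 0:2)
    cnt[[paste0("n", u, v)]] <- tcrossprod(I[[u + 1]], I[[v + 1]])
  dims <- dim(cnt$n00)
  r <- em_rf(cnt$n00, cnt$n01, cnt$n02, cnt$n10, cnt$n11, cnt$n12,
             cnt$n20, cnt$n21, cnt$n22)
  ll <- f2_loglik(r, cnt$n00, cnt$n01, cnt$n02, cnt$n10, cnt$n11, cnt$n12,
                  cnt$n20, cnt$n21, cnt$n22)
  ll0 <- f2_loglik(matrix(0.5, dims[1], dims[2]),
                   cnt$n00, cnt$n01, cnt$n02, cnt$n10, cnt$n11, cnt$n12,
                   cnt$n20, cnt$n21, cnt$n22)
  lod <- pmax((ll - ll0) / log(10), 0)
  r <- matrix(r, dims[1], dims[2]); lod <- matrix(lod, dims[1], dims[2])
  diag(r) <- 0; diag(lod) <- 0
  dimnames(r) <- dimnames(lod) <- list(rownames(R), rownames(R))
  list(r = r, lod = lod)
}

#' Group bins into linkage groups
#'
#' Single-linkage transitive closure over edges with r < `r_max` and
#' LOD >= `lod_min` (defaults 0.4 and 6). Groups are labeled by majority vote
#' of supplied framework anchors when available, else LG1..LGk in order of
#' first member.
#'
#' @param rf Output of [pairwise_rf()].
#' @param r_max,lod_min Edge thresholds.
#' @param anchor_labels Optional character vector (length = bins) of known
#'   group labels (NA where unknown).
#' @return Character vector of group labels per bin; singleton groups carry
#'   attribute `unplaced` listing their indices.
#' @export
group_bins <- function(rf, r_max = 0.4, lod_min = 6, anchor_labels = NULL) {
  k <- nrow(rf$r)
  adj <- rf$r < r_max & rf$lod >= lod_min
  diag(adj) <- FALSE
  comp <- integer(k); cur <- 0L
  for (i in seq_len(k)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        if (comp[v] != 0L) next
        comp[v] <- cur
        queue <- c(queue, which(adj[v, ] & comp == 0L))
      }
    }
  }
  labels <- sprintf("LG%d", comp)
  if (!is.null(anchor_labels)) {
    for (c in unique(comp)) {
      sel <- comp == c
      known <- anchor_labels[sel]
      known <- known[!is.na(known)]
      if (length(known)) {
        tab <- sort(table(known), decreasing = TRUE)
        labels[sel] <- names(tab)[1]
      }
    }
  }
  sizes <- table(comp)
  structure(labels, unplaced = which(comp %in% as.integer(
    names(sizes)[sizes == 1])))
}

# or-opt: relocate short segments (1-3 bins) to a better position; catches
# single misplaced bins that 2-opt segment reversal cannot repair
or_opt <- function(ord, rmat) {
  k <- length(ord)
  if (k < 4) return(ord)
  edge <- function(a, b) if (a < 1 || b > k) 0 else rmat[ord[a], ord[b]]
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (L in 1:3) {
      if (k - L < 2) next
      i <- 1
      while (i <= k - L + 1) {
        e <- i + L - 1
        removed <- edge(i - 1, i) + edge(e, e + 1) -
          (if (i > 1 && e < k) rmat[ord[i - 1], ord[e + 1]] else 0)
        best_delta <- -1e-12; best_j <- NA
        for (j in setdiff(0:k, seq(i - 1, e))) {
          # insert segment between positions j and j+1 (0 = front)
          old_edge <- if (j >= 1 && j + 1 <= k) rmat[ord[j], ord[j + 1]] else 0
          add <- (if (j >= 1) rmat[ord[j], ord[i]] else 0) +
            (if (j + 1 <= k) rmat[ord[e], ord[j + 1]] else 0) - old_edge
          delta <- add - removed
          if (delta < best_delta) { best_delta <- delta; best_j <- j }
        }
        if (!is.na(best_j)) {
          segv <- ord[i:e]
          rest <- ord[-(i:e)]
          jj <- best_j - if (best_j >= i) L else 0
          ord <- append(rest, segv, after = jj)
          improved <- TRUE
        } else i <- i + 1
      }
    }
  }
  ord
}

two_opt <- function(ord, rmat) {
  k <- length(ord)
  if (k < 4) return(ord)
  improved <- TRUE
  cost <- function(o) sum(rmat[cbind(o[-k], o[-1])])
  while (improved) {
    improved <- FALSE
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        # reverse ord[i..j]; only boundary edges change
        left <- if (i > 1) rmat[ord[i - 1], ord[i]] else 0
        right <- if (j < k) rmat[ord[j], ord[j + 1]] else 0
        nleft <- if (i > 1) rmat[ord[i - 1], ord[j]] else 0
        nright <- if (j < k) rmat[ord[i], ord[j + 1]] else 0
        if (nleft + nright < left + right - 1e-12) {
          ord[i:j] <- ord[j:i]
          improved <- TRUE
        }
      }
    }
  }
  ord
}

#' Order the bins of one linkage group
#'
#' Seeds the order with the first principal coordinate of the Kosambi
#' distance matrix, then improves it by alternating 2-opt reversals and
#' or-opt short-segment relocations minimizing the sum of adjacent
#' recombination fractions; the orientation is fixed deterministically
#' (first bin index below last). Cumulative cM is the running sum of
#' Kosambi-transformed adjacent fractions.
#'
#' @param rf Output of [pairwise_rf()] restricted to (or covering) the group.
#' @param members Integer indices of the group's bins.
#' @return list `order` (member indices in map order) and `cm` (cumulative
#'   cM along that order).
#' @export
order_bins <- function(rf, members) {
  if (length(members) < 2)
    return(list(order = members, cm = rep(0, length(members))))
  r <- rf$r[members, members, drop = FALSE]
  if (any(!is.finite(r))) stop("undefined estimates within group", call. = FALSE)
  d <- kosambi(pmin(r, 0.4999))
  k <- length(members)
  refine <- function(ord) {
    repeat {
      ord2 <- or_opt(two_opt(ord, r), r)
      if (identical(ord2, ord)) break
      ord <- ord2
    }
    ord
  }
  cost <- function(ord) sum(r[cbind(ord[-k], ord[-1])])
  # two deterministic seeds: principal-coordinate embedding (good when
  # distances are informative) and greedy nearest-neighbour chaining from the
  # most peripheral bin (robust when long-range r saturates at 0.5)
  seeds <- list(seq_len(k))
  if (k > 2) {
    pc <- tryCatch(suppressWarnings(cmdscale(stats::as.dist(d), k = 1)),
                   error = function(e) NULL)
    if (!is.null(pc)) seeds <- c(seeds, list(order(pc[, 1])))
    start <- which.max(rowSums(r))
    nn <- integer(k); used <- rep(FALSE, k)
    nn[1] <- start; used[start] <- TRUE
    for (s in 2:k) {
      cand <- which(!used)
      nn[s] <- cand[which.min(r[nn[s - 1], cand])]
      used[nn[s]] <- TRUE
    }
    seeds <- c(seeds, list(nn))
  }
  refined <- lapply(seeds, refine)
  ord <- refined[[which.min(vapply(refined, cost, numeric(1)))]]
  if (ord[1] > ord[length(ord)]) ord <- rev(ord)
  adj <- r[cbind(ord[-length(ord)], ord[-1])]
  cm <- c(0, cumsum(kosambi(pmin(adj, 0.4999))))
  list(order = members[ord], cm = cm)
}

#' Build the genetic map from an imputed genotype matrix
#'
#' End-to-end linkage stage: bins, pairwise rf, grouping, per-group ordering,
#' Kosambi distances.
#'
#' @param G Imputed genotype matrix (sites x individuals).
#' @param sites Site table aligned to `G` (`scaffold, pos`, optional `chrom`).
#' @param cfg A [pbm_config()].
#' @param anchor_labels Optional known group label per site (NA allowed);
#'   transferred to bins by first member.
#' @return list: `map` (a `genetic_map`), `bin_set`, `rf`, `groups`.
#' @export
map_from_genotypes <- function(G, sites, cfg = pbm_config(),
                               anchor_labels = NULL) {
  bs <- build_bins(G, sites)
  rf <- pairwise_rf(bs$representative)
  bin_anchor <- NULL
  if (!is.null(anchor_labels)) {
    first <- match(seq_len(nrow(bs$representative)), bs$membership)
    bin_anchor <- anchor_labels[first]
  }
  groups <- group_bins(rf, cfg$rf_max, cfg$lod_min, bin_anchor)
  rows <- list()
  for (g in unique(groups)) {
    members <- which(groups == g)
    ob <- order_bins(rf, members)
    b <- bs$bins[ob$order, , drop = FALSE]
    rows[[g]] <- data.frame(group = g, bin = b$bin, cm = ob$cm,
                            n_snps = b$n_snps,
                            scaffold = b$scaffold %||% NA_character_,
                            start = b$start %||% NA_integer_,
                            end = b$end %||% NA_integer_,
                            stringsAsFactors = FALSE)
  }
  ord <- order(vapply(rows, function(x) x$group[1], character(1)))
  map <- build_genetic_map(do.call(rbind, rows[ord]))
  list(map = map, bin_set = bs, rf = rf, groups = groups)
}

#' Map-quality matrix (linkage heat map analogue)
#'
#' For an ordered bin list: upper triangle holds pairwise similarity scores of
#' the representative genotype vectors, lower triangle 1 - 2 r clipped to
#' `[0, 1]`; a correct order concentrates high values on the diagonal.
#'
#' @param R Representative genotype matrix in map order (bins x individuals).
#' @param rmat Matching recombination-fraction matrix (same order).
#' @return Numeric matrix with 1.0 on the diagonal.
#' @export
quality_matrix <- function(R, rmat) {
  I <- geno_indicators(R)
  nonmiss <- I$I0 + I$I1 + I$I2
  n <- tcrossprod(nonmiss)
  match_ <- tcrossprod(I$I0) + tcrossprod(I$I1) + tcrossprod(I$I2)
  half <- tcrossprod(I$I1, I$I0 + I$I2) + tcrossprod(I$I0 + I$I2, I$I1)
  sim <- ifelse(n > 0, (match_ + 0.5 * half) / n, NA_real_)
  rec <- pmin(pmax(1 - 2 * rmat, 0), 1)
  out <- rec
  out[upper.tri(out)] <- sim[upper.tri(sim)]
  diag(out) <- 1
  out
}
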