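# Recombination landscape, SNP-density scan, and centromere localization from
# filtered retrotransposon homology hits.

#' Recombination-rate profile along anchored bins
#'
#' For each adjacent-bin interval of a chromosome, rate = (cM span) / (Mb
#' span). Intervals with rate below `suppression_rate` (default 1.0 cM/Mb)
#' are classed "suppression", all others "hotspot". Zero physical span between
#' distinct bins skips the interval with a warning.
#'
#' @param bins data.frame `chrom, cm, mid_bp` ordered by map position within
#'   chromosome.
#' @param suppression_rate Threshold in cM/Mb.
#' @return data.frame `chrom, start, end, cm_span, rate, class` (1-based bp),
#'   with attribute `mean_rate` (per-chromosome named vector).
#' @export
recombination_profile <- function(bins, suppression_rate = 1.0) {
  out <- list()
  means <- c()
  for (ch in unique(bins$chrom)) {
    x <- bins[bins$chrom == ch, , drop = FALSE]
    if (nrow(x) < 2) next
    dbp <- diff(x$mid_bp); dcm <- abs(diff(x$cm))
    zero <- dbp == 0
    if (any(zero)) warning("zero physical span interval skipped on ", ch)
    rate <- dcm[!zero] / (abs(dbp[!zero]) / 1e6)
    out[[ch]] <- data.frame(
      chrom = ch,
      start = as.integer(pmin(x$mid_bp[-nrow(x)], x$mid_bp[-1]))[!zero],
      end = as.integer(pmax(x$mid_bp[-nrow(x)], x$mid_bp[-1]))[!zero],
      cm_span = dcm[!zero], rate = rate,
      class = ifelse(rate < suppression_rate, "suppression", "hotspot"),
      stringsAsFactors = FALSE)
    means[ch] <- sum(dcm[!zero]) / (sum(abs(dbp[!zero])) / 1e6)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "mean_rate") <- means
  res
}

#' SNP density in fixed windows
#'
#' Counts SNPs per half-open window (default 50 kb) along each chromosome;
#' the final partial window is retained with its true width.
#'
#' @param positions data.frame `chrom, pos` (1-based).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window_bp Window width (default 50 kb).
#' @return data.frame `chrom, start, end, width, count` (1-based inclusive
#'   windows).
#' @export
snp_density_scan <- function(positions, chrom_lengths, window_bp = 5e4) {
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(1, L, by = window_bp)
    ends <- pmin(starts + window_bp - 1, L)
    p <- positions$pos[positions$chrom == ch]
    cnt <- if (length(p))
      tabulate(findInterval(p, starts), length(starts)) else
      integer(length(starts))
    data.frame(chrom = ch, start = as.integer(starts), end = as.integer(ends),
               width = as.integer(ends - starts + 1), count = cnt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Detect SNP-poor regions
#'
#' Maximal runs of at least `min_run` (default 20) consecutive windows whose
#' count falls below `low_threshold` are merged into regions. The default
#' threshold is 10% of the genome-wide median window count (the notion of
#' "low frequency" is a package contract, stamped into output).
#'
#' @param windows Output of [snp_density_scan()].
#' @param min_run Minimum consecutive low windows (default 20).
#' @param low_threshold Count threshold; default `0.1 * median(count)`.
#' @return data.frame `chrom, start, end, n_windows, label` of regions, with
#'   attribute `low_threshold`.
#' @export
detect_snp_poor <- function(windows, min_run = 20, low_threshold = NULL) {
  low_threshold <- low_threshold %||% (0.1 * median(windows$count))
  out <- list()
  for (ch in unique(windows$chrom)) {
    x <- windows[windows$chrom == ch, , drop = FALSE]
    low <- x$count < low_threshold
    r <- rle(low)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (i in which(r$values & r$lengths >= min_run)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = x$start[starts[i]], end = x$end[ends[i]],
        n_windows = r$lengths[i], label = "snp_poor",
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_windows = integer(), label = character(),
               stringsAsFactors = FALSE)
  attr(res, "low_threshold") <- low_threshold
  res
}

#' Filter homology hits on identity and e-value
#'
#' @param hits Hit table ([read_hit_table()] shape).
#' @param min_identity Minimum percent identity (default 80, inclusive).
#' @param max_evalue Maximum e-value (default 1e-20, inclusive).
#' @return The retained hits.
#' @export
filter_hits <- function(hits, min_identity = 80, max_evalue = 1e-20) {
  hits[hits$identity >= min_identity & hits$evalue <= max_evalue, ,
       drop = FALSE]
}

#' Centromere interval from clustered hit positions
#'
#' Median of hit midpoints with its distribution-free 95% confidence interval
#' from order statistics: with n sorted positions the CI spans the
#' `qbinom(0.025, n, 1/2)`-th through `(n + 1 - that)`-th order statistics
#' (e.g. ranks 8-18 at n = 25). Below `min_hits` the chromosome is reported
#' as having no detectable centromeric region.
#'
#' @param positions Hit midpoint positions for one chromosome.
#' @param min_hits Minimum hit count (default 5).
#' @return list `present, n, median, lower, upper` (`present = FALSE` carries
#'   only `n`).
#' @export
centromere_interval <- function(positions, min_hits = 5) {
  n <- length(positions)
  if (n < min_hits) return(list(present = FALSE, n = n))
  x <- sort(positions)
  l <- qbinom(0.025, n, 0.5)
  if (l < 1) l <- 1
  u <- n + 1 - l
  list(present = TRUE, n = n, median = median(x), lower = x[l], upper = x[u])
}

#' Scan all chromosomes for centromeric regions
#'
#' Filters hits, optionally restricts to a query subset, pools hits across
#' queries per chromosome (`pooled = TRUE`, the mingled-queries recipe) or
#' intersects per-query intervals (`pooled = FALSE`), and localizes the
#' centromere per chromosome.
#'
#' @param hits Hit table.
#' @param queries Optional query ids to keep (default all).
#' @param min_identity,max_evalue Filter thresholds.
#' @param min_hits Minimum hits per chromosome.
#' @param pooled Pool queries per chromosome (default TRUE).
#' @return data.frame `chrom, present, n, median, lower, upper`.
#' @export
centromere_scan <- function(hits, queries = NULL, min_identity = 80,
                            max_evalue = 1e-20, min_hits = 5, pooled = TRUE) {
  h <- filter_hits(hits, min_identity, max_evalue)
  if (!is.null(queries)) h <- h[h$query %in% queries, , drop = FALSE]
  mid <- (h$sstart + h$send) / 2
  rows <- lapply(unique(h$subject), function(ch) {
    sel <- h$subject == ch
    if (pooled) {
      ci <- centromere_interval(mid[sel], min_hits)
    } else {
      per <- lapply(unique(h$query[sel]), function(q)
        centromere_interval(mid[sel & h$query == q], min_hits))
      per <- Filter(function(x) x$present, per)
      ci <- if (!length(per)) list(present = FALSE, n = sum(sel)) else
        list(present = TRUE, n = sum(sel),
             median = median(vapply(per, `[[`, 0, "median")),
             lower = min(vapply(per, `[[`, 0, "lower")),
             upper = max(vapply(per, `[[`, 0, "upper")))
    }
    data.frame(chrom = ch, present = ci$present, n = ci$n,
               median = ci$median %||% NA_real_,
               lower = ci$lower %||% NA_real_,
               upper = ci$upper %||% NA_real_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-subgenome homology-hit summary
#'
#' Per-chromosome filtered-hit counts, subgenome means, and a Welch two-sample
#' t-test contrasting the two subgenomes' per-chromosome counts.
#'
#' @param hits Filtered hit table.
#' @param subgenome_of Named character vector chromosome -> subgenome
#'   (e.g. "A"/"D"); chromosomes with zero hits still contribute a zero count.
#' @return list `counts` (per chromosome), `means` (per subgenome), `t_test`
#'   (htest or NULL when a subgenome has < 2 chromosomes).
#' @export
subgenome_hit_summary <- function(hits, subgenome_of) {
  counts <- vapply(names(subgenome_of),
                   function(ch) sum(hits$subject == ch), integer(1))
  sub <- subgenome_of[names(counts)]
  means <- tapply(counts, sub, mean)
  tt <- NULL
  if (all(table(sub) >= 2) && length(unique(sub)) == 2) {
    tt <- tryCatch(t.test(counts ~ factor(sub)), error = function(e) {
      # zero-variance groups: a well-defined degenerate contrast
      if (diff(range(means)) == 0)
        structure(list(statistic = c(t = 0), p.value = 1,
                       method = "Welch (degenerate: constant data)"),
                  class = "htest")
      else NULL
    })
  }
  list(counts = counts, means = means, t_test = tt)
}
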