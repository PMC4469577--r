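# Comparative stage: chain synteny anchors between the tetraploid map and a
# diploid reference genome into oriented blocks, then call reciprocal
# translocations, simple translocations and inversions, with interval-size
# arithmetic matching standard Mb reporting.

#' Chain synteny anchors into blocks
#'
#' Anchors (one best reference location each) sorted by map position within a
#' group are chained into maximal runs on one reference chromosome with a
#' consistent coordinate direction; up to `max_gap` consecutive discordant
#' anchors are skipped as outliers, more close the block. Runs with fewer
#' than `min_anchors` anchors are discarded.
#'
#' @param anchors data.frame `group, cm, ref_chrom, ref_pos` sorted by `cm`
#'   within group.
#' @param min_anchors Minimum anchors per block (default 10).
#' @param max_gap Discordant anchors tolerated inside a block (default 3).
#' @return data.frame `group, ref_chrom, orientation, n_anchors, cm_start,
#'   cm_end, ref_start, ref_end`.
#' @export
build_synteny_blocks <- function(anchors, min_anchors = 10, max_gap = 3) {
  blocks <- list()
  flush <- function(run) {
    if (nrow(run) >= min_anchors) {
      dir <- sign(cor(seq_len(nrow(run)), run$ref_pos, method = "spearman"))
      if (is.na(dir) || dir == 0) dir <- 1
      blocks[[length(blocks) + 1]] <<- data.frame(
        group = run$group[1], ref_chrom = run$ref_chrom[1],
        orientation = if (dir > 0) "+" else "-", n_anchors = nrow(run),
        cm_start = min(run$cm), cm_end = max(run$cm),
        ref_start = min(run$ref_pos), ref_end = max(run$ref_pos),
        stringsAsFactors = FALSE)
    }
  }
  for (g in unique(anchors$group)) {
    x <- anchors[anchors$group == g, , drop = FALSE]
    x <- x[order(x$cm), , drop = FALSE]
    run <- x[0, ]; dir <- 0L; gap <- 0L; pending <- x[0, ]
    for (i in seq_len(nrow(x))) {
      a <- x[i, ]
      consistent <- nrow(run) == 0 ||
        (a$ref_chrom == run$ref_chrom[1] &&
           (nrow(run) == 1 || dir == 0 ||
              sign(a$ref_pos - run$ref_pos[nrow(run)]) %in% c(0, dir)))
      if (consistent) {
        run <- rbind(run, a)
        if (nrow(run) >= 2 && dir == 0)
          dir <- sign(run$ref_pos[nrow(run)] - run$ref_pos[nrow(run) - 1])
        gap <- 0L; pending <- x[0, ]
      } else {
        pending <- rbind(pending, a)
        gap <- gap + 1L
        if (gap > max_gap) {
          flush(run)
          # restart from the buffered discordant anchors
          run <- x[0, ]; dir <- 0L; gap <- 0L
          for (j in seq_len(nrow(pending))) {
            b <- pending[j, ]
            if (nrow(run) == 0 || (b$ref_chrom == run$ref_chrom[1] &&
                (nrow(run) == 1 || dir == 0 ||
                   sign(b$ref_pos - run$ref_pos[nrow(run)]) %in% c(0, dir)))) {
              run <- rbind(run, b)
              if (nrow(run) >= 2 && dir == 0)
                dir <- sign(run$ref_pos[nrow(run)] - run$ref_pos[nrow(run) - 1])
            }
          }
          pending <- x[0, ]
        }
      }
    }
    flush(run)
  }
  if (!length(blocks))
    return(data.frame(group = character(), ref_chrom = character(),
                      orientation = character(), n_anchors = integer(),
                      cm_start = numeric(), cm_end = numeric(),
                      ref_start = numeric(), ref_end = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, blocks)
}

#' Interval length in Mb
#'
#' `(end - start) / 1e6` rounded to two decimals (simple coordinate
#' difference, matching standard Mb reporting of genomic intervals).
#'
#' @param start_bp,end_bp Interval coordinates, `end_bp >= start_bp`.
#' @return Length in Mb, two decimals.
#' @examples
#' interval_length_mb(33736, 28298512)  # 28.26
#' @export
interval_length_mb <- function(start_bp, end_bp) {
  if (any(end_bp < start_bp)) stop("end < start", call. = FALSE)
  round((end_bp - start_bp) / 1e6, 2)
}

#' Interval as percent of a chromosome
#'
#' @param interval_mb Interval length (Mb).
#' @param chrom_length_mb Chromosome length (Mb).
#' @return Percent, two decimals.
#' @export
fraction_of_chromosome <- function(interval_mb, chrom_length_mb) {
  if (any(chrom_length_mb <= 0)) stop("chromosome length must be > 0",
                                      call. = FALSE)
  if (any(interval_mb > chrom_length_mb)) stop("interval exceeds chromosome",
                                               call. = FALSE)
  round(100 * interval_mb / chrom_length_mb, 2)
}

#' Detect rearrangements from synteny blocks
#'
#' Given each group's expected ("home") reference chromosome: a reciprocal
#' translocation is the exchange pattern where two groups each carry a block
#' homing to the other's chromosome; a lone foreign-chromosome block in an
#' otherwise homogeneous group is a simple translocation; a block whose
#' orientation opposes the majority orientation of same-chromosome blocks in
#' its group is an inversion.
#'
#' @param blocks From [build_synteny_blocks()].
#' @param home Named character vector group -> home reference chromosome.
#' @param ref_lengths_mb Optional named vector of reference chromosome
#'   lengths in Mb (enables the percent column).
#' @return data.frame `type, groups, ref_chrom, cm_start, cm_end, ref_start,
#'   ref_end, size_mb, pct_of_chrom`.
#' @export
detect_rearrangements <- function(blocks, home, ref_lengths_mb = NULL) {
  calls <- list()
  add <- function(type, groups, b) {
    size <- interval_length_mb(b$ref_start, b$ref_end)
    pct <- if (!is.null(ref_lengths_mb) && b$ref_chrom %in% names(ref_lengths_mb))
      fraction_of_chromosome(size, ref_lengths_mb[[b$ref_chrom]]) else NA_real_
    calls[[length(calls) + 1]] <<- data.frame(
      type = type, groups = groups, ref_chrom = b$ref_chrom,
      cm_start = b$cm_start, cm_end = b$cm_end,
      ref_start = b$ref_start, ref_end = b$ref_end,
      size_mb = size, pct_of_chrom = pct, stringsAsFactors = FALSE)
  }
  for (g in names(home))
    if (!g %in% blocks$group) warning("group without blocks skipped: ", g)
  foreign <- blocks[blocks$ref_chrom != home[blocks$group], , drop = FALSE]
  used <- rep(FALSE, nrow(foreign))
  # reciprocal: group X holds home[Y], group Y holds home[X]
  if (nrow(foreign) >= 2) {
    for (i in seq_len(nrow(foreign) - 1)) {
      for (j in seq(i + 1, nrow(foreign))) {
        if (used[i] || used[j]) next
        bi <- foreign[i, ]; bj <- foreign[j, ]
        if (bi$group != bj$group &&
            bi$ref_chrom == home[[bj$group]] &&
            bj$ref_chrom == home[[bi$group]]) {
          pair <- sort(c(bi$group, bj$group))
          # one symmetric call per exchange; annotated with the block of the
          # alphabetically first group
          add("reciprocal_translocation", paste(pair, collapse = "/"),
              if (bi$group == pair[1]) bi else bj)
          used[i] <- used[j] <- TRUE
        }
      }
    }
  }
  for (i in which(!used))
    add("simple_translocation", foreign$group[i], foreign[i, ])
  # inversions: minority orientation among home-chromosome blocks of a group
  at_home <- blocks[blocks$ref_chrom == home[blocks$group], , drop = FALSE]
  for (g in unique(at_home$group)) {
    x <- at_home[at_home$group == g, , drop = FALSE]
    tab <- tapply(x$n_anchors, x$orientation, sum)
    if (length(tab) < 2) next
    minority <- names(tab)[which.min(tab)]
    for (i in which(x$orientation == minority)) add("inversion", g, x[i, ])
  }
  if (!length(calls))
    return(data.frame(type = character(), groups = character(),
                      ref_chrom = character(), cm_start = numeric(),
                      cm_end = numeric(), ref_start = numeric(),
                      ref_end = numeric(), size_mb = numeric(),
                      pct_of_chrom = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, calls)
}
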