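# Mis-assembly detection and pseudomolecule anchoring: 201-bp SNP segments,
# runs of >= 10 consecutive segments sharing a genetic position, breakpoints
# between discordant stable runs, scaffold splitting, ordering by bin cM and
# orientation by cM-vs-coordinate correlation.

#' Extract SNP-centered segments from scaffolds
#'
#' One fixed-width segment (default 201 bp: 100 bp each side) per mapped SNP;
#' SNPs within 100 bp of a scaffold edge are skipped and counted.
#'
#' @param snps Site table (`scaffold, pos`).
#' @param scaffold_lengths Named integer vector of scaffold lengths.
#' @param segment_bp Segment width (odd, default 201).
#' @return data.frame `scaffold, pos, start, end` (1-based inclusive) with
#'   attribute `n_skipped_edge`.
#' @export
extract_segments <- function(snps, scaffold_lengths, segment_bp = 201L) {
  stopifnot(segment_bp %% 2 == 1)
  half <- (segment_bp - 1L) %/% 2L
  len <- scaffold_lengths[snps$scaffold]
  if (anyNA(len)) stop("scaffold length missing", call. = FALSE)
  ok <- snps$pos - half >= 1L & snps$pos + half <= len
  out <- data.frame(scaffold = snps$scaffold[ok], pos = snps$pos[ok],
                    start = as.integer(snps$pos[ok] - half),
                    end = as.integer(snps$pos[ok] + half),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped_edge") <- sum(!ok)
  out
}

#' Attach genetic positions to segments and apply mapping filters
#'
#' Drops segments lacking a unique full-length match on the assembly (the
#' uniqueness/match-length flags come from an upstream aligner, or from exact
#' search on synthetic genomes) and joins each survivor to its SNP's bin,
#' linkage group and cM.
#'
#' @param segments From [extract_segments()].
#' @param genetic_positions data.frame `scaffold, pos, bin, group, cm` for
#'   mapped SNPs.
#' @param unique Logical vector per segment (default all TRUE).
#' @param match_len Integer matched bases per segment (default full width).
#' @param segment_bp Required match width (default 201).
#' @return Segments with `bin, group, cm` columns; unmapped SNPs dropped.
#' @export
assign_segment_positions <- function(segments, genetic_positions,
                                     unique = NULL, match_len = NULL,
                                     segment_bp = 201L) {
  unique <- unique %||% rep(TRUE, nrow(segments))
  match_len <- match_len %||% rep(segment_bp, nrow(segments))
  keep <- unique & match_len >= segment_bp
  seg <- segments[keep, , drop = FALSE]
  key_s <- paste0(seg$scaffold, ":", seg$pos)
  key_g <- paste0(genetic_positions$scaffold, ":", genetic_positions$pos)
  idx <- match(key_s, key_g)
  seg$bin <- genetic_positions$bin[idx]
  seg$group <- genetic_positions$group[idx]
  seg$cm <- genetic_positions$cm[idx]
  seg <- seg[!is.na(seg$bin), , drop = FALSE]
  seg[order(seg$scaffold, seg$pos), , drop = FALSE]
}

# maximal runs of consecutive segments in the same bin, per scaffold
stable_runs <- function(seg, min_run) {
  runs <- list()
  for (sc in unique(seg$scaffold)) {
    x <- seg[seg$scaffold == sc, , drop = FALSE]
    rid <- cumsum(c(1L, as.integer(x$bin[-1] != x$bin[-nrow(x)])))
    for (r in unique(rid)) {
      sel <- rid == r
      if (sum(sel) >= min_run)
        runs[[length(runs) + 1]] <- data.frame(
          scaffold = sc, group = x$group[sel][1], cm = x$cm[sel][1],
          bin = x$bin[sel][1], n_segments = sum(sel),
          first_pos = min(x$pos[sel]), last_pos = max(x$pos[sel]),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(runs)) return(NULL)
  do.call(rbind, runs)
}

#' Detect scaffold mis-assemblies
#'
#' Stable runs are maximal stretches of at least `min_run` consecutive
#' segments sharing a genetic position (same bin, hence same group and cM). A
#' breakpoint is emitted between adjacent stable runs of one scaffold whose
#' genetic positions disagree: different linkage groups, or -- within a group
#' -- a cM discontinuity above `cm_jump_tol` that is not bridged by the
#' intervening (short-bin) segments: the ordered cM sequence from the left
#' run through any segments between the runs to the right run must step by
#' more than the tolerance somewhere. This distinguishes a genuine junction
#' from a recombination-dense stretch whose bins are individually too short
#' to form stable runs. Breakpoints are placed at the midpoint of the largest
#' offending step (the inter-run midpoint when no segments intervene) and
#' classified homoeologous / interchromosomal / intrachromosomal by the A/D
#' pairing convention.
#'
#' @param seg Assigned segments from [assign_segment_positions()].
#' @param min_run Minimum segments per stable run (default 10).
#' @param cm_jump_tol Intra-group cM jump tolerance (default 5).
#' @param bin_rf Optional recombination-fraction matrix with bin ids as
#'   dimnames (e.g. `pairwise_rf()$r`). When supplied, an intra-group
#'   candidate additionally requires direct evidence: the Kosambi distance
#'   implied by r between the two flanking runs' bins must itself exceed the
#'   tolerance. This suppresses spurious jumps caused by cumulative-cM noise
#'   or by a genotype pattern recurring at a second nearby location.
#' @return data.frame of breakpoints (`scaffold, left_pos, right_pos,
#'   breakpoint, left_group, left_cm, right_group, right_cm, class`), plus
#'   attribute `unanchorable` (scaffolds with zero stable runs).
#' @export
detect_misassemblies <- function(seg, min_run = 10, cm_jump_tol = 5,
                                 bin_rf = NULL) {
  runs <- stable_runs(seg, min_run)
  empty <- data.frame(scaffold = character(), left_pos = integer(),
                      right_pos = integer(), breakpoint = integer(),
                      left_group = character(), left_cm = numeric(),
                      right_group = character(), right_cm = numeric(),
                      class = character(), stringsAsFactors = FALSE)
  all_sc <- unique(seg$scaffold)
  if (is.null(runs)) {
    attr(empty, "unanchorable") <- all_sc
    return(empty)
  }
  out <- list()
  for (sc in unique(runs$scaffold)) {
    x <- runs[runs$scaffold == sc, , drop = FALSE]
    x <- x[order(x$first_pos), , drop = FALSE]
    if (nrow(x) < 2) next
    segsc <- seg[seg$scaffold == sc, , drop = FALSE]
    segsc <- segsc[order(segsc$pos), , drop = FALSE]
    for (i in seq_len(nrow(x) - 1)) {
      a <- x[i, ]; b <- x[i + 1, ]
      between <- segsc[segsc$pos > a$last_pos & segsc$pos < b$first_pos, ,
                       drop = FALSE]
      bp_pos <- as.integer(floor((a$last_pos + b$first_pos) / 2))
      if (a$group != b$group) {
        differs <- TRUE
      } else if (abs(a$cm - b$cm) <= cm_jump_tol) {
        differs <- FALSE
      } else {
        # same group, large jump: only a discontinuity unbridged by the
        # intervening same-group segments counts as a breakpoint
        bridge_ok <- nrow(between) > 0 && all(between$group == a$group)
        cms <- c(a$cm, if (bridge_ok) between$cm, b$cm)
        pts <- c(a$last_pos, if (bridge_ok) between$pos, b$first_pos)
        steps <- abs(diff(cms))
        differs <- any(steps > cm_jump_tol)
        if (differs && !is.null(bin_rf) &&
            all(c(a$bin, b$bin) %in% rownames(bin_rf))) {
          direct <- kosambi(min(bin_rf[a$bin, b$bin], 0.4999))
          differs <- direct > cm_jump_tol
        }
        if (differs) {
          j <- which.max(steps)
          bp_pos <- as.integer(floor((pts[j] + pts[j + 1]) / 2))
        }
      }
      if (!differs) next
      out[[length(out) + 1]] <- data.frame(
        scaffold = sc, left_pos = a$last_pos, right_pos = b$first_pos,
        breakpoint = bp_pos,
        left_group = a$group, left_cm = a$cm,
        right_group = b$group, right_cm = b$cm,
        class = classify_pairing(a$group, b$group), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  attr(res, "unanchorable") <- setdiff(all_sc, runs$scaffold)
  res
}

#' Split chimeric scaffolds and anchor pieces into pseudomolecules
#'
#' Chimeras are split at breakpoint midpoints. Each piece is assigned the
#' linkage group of its stable runs, ordered within the group by the median
#' cM of its segments, and oriented by the sign of the Spearman correlation
#' between cM and scaffold coordinate (below `orient_min_rho` in magnitude the
#' piece is flagged unoriented `?`). Pieces shorter than `anchor_min_len` are
#' reported unplaced. The AGP layout inserts fixed-width gaps between placed
#' components.
#'
#' @param scaffold_lengths Named integer vector.
#' @param breakpoints From [detect_misassemblies()].
#' @param seg Assigned segments (for piece group / cM / orientation).
#' @param anchor_min_len Minimum piece length to place (default 500 kb).
#' @param orient_min_rho Orientation confidence threshold (default 0.5).
#' @param gap_bp AGP gap width (default 100).
#' @return list: `pieces` (piece, scaffold, start, end, length, group,
#'   median_cm, orientation, placed), `layout` (AGP-shaped data.frame for
#'   placed pieces).
#' @export
split_and_anchor <- function(scaffold_lengths, breakpoints, seg,
                             anchor_min_len = 5e5, orient_min_rho = 0.5,
                             gap_bp = 100L) {
  pieces <- list()
  for (sc in names(scaffold_lengths)) {
    bp <- sort(breakpoints$breakpoint[breakpoints$scaffold == sc])
    bounds <- c(0L, bp, scaffold_lengths[[sc]])
    for (i in seq_len(length(bounds) - 1)) {
      pieces[[length(pieces) + 1]] <- data.frame(
        piece = if (length(bp)) sprintf("%s_p%d", sc, i) else sc,
        scaffold = sc, start = bounds[i] + 1L, end = bounds[i + 1],
        stringsAsFactors = FALSE)
    }
  }
  pieces <- do.call(rbind, pieces)
  pieces$length <- pieces$end - pieces$start + 1L
  pieces$group <- NA_character_
  pieces$median_cm <- NA_real_
  pieces$orientation <- "?"
  for (i in seq_len(nrow(pieces))) {
    x <- seg[seg$scaffold == pieces$scaffold[i] &
               seg$pos >= pieces$start[i] & seg$pos <= pieces$end[i], ,
             drop = FALSE]
    if (!nrow(x)) next
    grp <- unique(x$group)
    if (length(grp) > 1) {
      tab <- sort(table(x$group), decreasing = TRUE)
      # after a correct split each piece should be single-group; tolerate
      # stray segments below 5% but refuse a genuinely mixed piece
      if (tab[1] / nrow(x) < 0.95)
        stop("piece spans multiple groups after splitting: ",
             pieces$piece[i], call. = FALSE)
      grp <- names(tab)[1]
      x <- x[x$group == grp, , drop = FALSE]
    }
    pieces$group[i] <- grp
    pieces$median_cm[i] <- median(x$cm)
    if (nrow(x) >= 2 && stats::sd(x$cm) > 0) {
      rho <- suppressWarnings(cor(x$pos, x$cm, method = "spearman"))
      if (!is.na(rho) && abs(rho) >= orient_min_rho)
        pieces$orientation[i] <- if (rho >= 0) "+" else "-"
    } else if (nrow(x) >= 1) {
      pieces$orientation[i] <- "+"  # single-bin piece: orientation arbitrary
    }
  }
  pieces$placed <- !is.na(pieces$group) & pieces$length >= anchor_min_len
  layout <- list()
  for (g in sort(unique(pieces$group[pieces$placed]))) {
    x <- pieces[pieces$placed & pieces$group == g, , drop = FALSE]
    x <- x[order(x$median_cm, x$piece), , drop = FALSE]
    for (i in seq_len(nrow(x))) {
      if (i > 1)
        layout[[length(layout) + 1]] <- data.frame(
          object = g, part = NA, type = "N", id = NA, comp_start = NA,
          comp_end = NA, orientation = NA, gap_len = gap_bp,
          stringsAsFactors = FALSE)
      layout[[length(layout) + 1]] <- data.frame(
        object = g, part = NA, type = "W", id = x$piece[i],
        comp_start = x$start[i], comp_end = x$end[i],
        orientation = if (x$orientation[i] == "?") "+" else x$orientation[i],
        gap_len = NA, stringsAsFactors = FALSE)
    }
  }
  layout <- if (length(layout)) do.call(rbind, layout) else NULL
  list(pieces = pieces, layout = layout)
}

#' Per-SNP genetic positions from a fitted map
#'
#' Joins every binned SNP to its bin's linkage group and cumulative cM — the
#' `genetic_positions` input of [assign_segment_positions()].
#'
#' @param mapres Result of [map_from_genotypes()].
#' @param sites Site table aligned to the genotype matrix the map was built
#'   from (`scaffold, pos`).
#' @return data.frame `scaffold, pos, bin, group, cm` (set-aside sites
#'   dropped).
#' @export
genetic_positions <- function(mapres, sites) {
  bs <- mapres$bin_set
  ids <- rownames(bs$representative)
  binrow <- match(mapres$map$bins$bin, ids)
  cm <- rep(NA_real_, length(ids)); grp <- rep(NA_character_, length(ids))
  cm[binrow] <- mapres$map$bins$cm
  grp[binrow] <- mapres$map$bins$group
  mem <- bs$membership
  out <- data.frame(scaffold = sites$scaffold, pos = sites$pos,
                    bin = ids[mem], group = grp[mem], cm = cm[mem],
                    stringsAsFactors = FALSE)
  out[!is.na(out$bin), , drop = FALSE]
}
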