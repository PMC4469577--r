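# Readers/writers for the pipeline's on-disk formats. All tabular outputs are
# 1-based inclusive except BED, which is 0-based half-open; each writer stamps
# the dialect into a header comment.

ALLELES <- c("A", "C", "G", "T")

#' Construct an allele-count table
#'
#' The pipeline's raw input: per-site read counts by allele for one sample,
#' derived upstream from alignments (uniquely mapped, MQ > 20 reads are the
#' converter contract; this package never touches BAMs).
#'
#' @param scaffold Character vector of scaffold ids.
#' @param pos 1-based positions, strictly increasing within each scaffold.
#' @param counts Integer matrix with columns A, C, G, T (one row per site).
#' @param sample_id Sample name.
#' @return A `data.frame` of class `allele_counts` with columns
#'   `scaffold, pos, nA, nC, nG, nT` and attribute `sample_id`.
#' @export
allele_counts <- function(scaffold, pos, counts, sample_id = "sample") {
  counts <- as.matrix(counts)
  stopifnot(length(scaffold) == length(pos), nrow(counts) == length(pos),
            ncol(counts) == 4)
  if (any(counts < 0)) stop("negative allele count", call. = FALSE)
  tab <- data.frame(scaffold = as.character(scaffold), pos = as.integer(pos),
                    nA = as.integer(counts[, 1]), nC = as.integer(counts[, 2]),
                    nG = as.integer(counts[, 3]), nT = as.integer(counts[, 4]),
                    stringsAsFactors = FALSE)
  validate_allele_counts(tab)
  attr(tab, "sample_id") <- sample_id
  class(tab) <- c("allele_counts", "data.frame")
  tab
}

validate_allele_counts <- function(tab) {
  for (sc in unique(tab$scaffold)) {
    p <- tab$pos[tab$scaffold == sc]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on scaffold ", sc, call. = FALSE)
  }
  invisible(tab)
}

#' Read / write allele-count tables
#'
#' TSV with header `scaffold pos nA nC nG nT` (1-based positions). The
#' reader validates the table invariants and reports the offending line on
#' failure; `write_allele_counts(read_allele_counts(f))` reproduces the
#' canonical form of `f` byte for byte.
#'
#' @param path File path.
#' @param tab An `allele_counts` table.
#' @param sample_id Optional sample id override (defaults to the file stem).
#' @return `read_allele_counts` returns an `allele_counts` table.
#' @export
read_allele_counts <- function(path, sample_id = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop_parse(path, 0L, "empty file")
  hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, c("scaffold", "pos", "nA", "nC", "nG", "nT")))
    stop_parse(path, 1L, "unexpected header")
  body <- lines[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  n <- length(body)
  scaffold <- character(n); num <- matrix(NA_integer_, n, 5)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) != 6) stop_parse(path, i + 1L, "expected 6 columns")
    v <- suppressWarnings(as.integer(f[2:6]))
    if (anyNA(v)) stop_parse(path, i + 1L, "non-integer field")
    if (any(v[2:5] < 0)) stop_parse(path, i + 1L, "negative count")
    scaffold[i] <- f[1]; num[i, ] <- v
  }
  tab <- allele_counts(scaffold, num[, 1], num[, 2:5],
                       sample_id = sample_id %||%
                         sub("\\.[^.]*$", "", basename(path)))
  tab
}

#' @rdname read_allele_counts
#' @export
write_allele_counts <- function(tab, path) {
  stopifnot(inherits(tab, "allele_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("scaffold\tpos\tnA\tnC\tnG\tnT", con)
  if (nrow(tab))
    writeLines(paste(tab$scaffold, tab$pos, tab$nA, tab$nC, tab$nG, tab$nT,
                     sep = "\t"), con)
  invisible(path)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Parses the standard 12-column tab-separated dialect (query, subject,
#' identity, length, mismatches, gap opens, qstart, qend, sstart, send,
#' evalue, bitscore). Subject coordinates are normalized to 1-based inclusive
#' `sstart <= send` with strand `-` when the raw pair was descending.
#'
#' @param path File path.
#' @return data.frame with columns `query, subject, identity, length,
#'   mismatches, gapopens, qstart, qend, sstart, send, evalue, bitscore,
#'   strand`.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- data.frame(query = character(), subject = character(),
                      identity = numeric(), length = integer(),
                      mismatches = integer(), gapopens = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      strand = character(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields))
    if (length(fields[[i]]) != 12)
      stop_parse(path, i, "expected 12 columns")
  m <- do.call(rbind, fields)
  ev <- suppressWarnings(as.numeric(m[, 11]))
  if (anyNA(ev)) stop_parse(path, which(is.na(ev))[1], "unparsable e-value")
  s1 <- as.integer(m[, 9]); s2 <- as.integer(m[, 10])
  data.frame(query = m[, 1], subject = m[, 2],
             identity = as.numeric(m[, 3]), length = as.integer(m[, 4]),
             mismatches = as.integer(m[, 5]), gapopens = as.integer(m[, 6]),
             qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
             sstart = pmin(s1, s2), send = pmax(s1, s2),
             evalue = ev, bitscore = as.numeric(m[, 12]),
             strand = ifelse(s1 > s2, "-", "+"), stringsAsFactors = FALSE)
}

#' Write genomic intervals as BED
#'
#' Converts the package's 1-based inclusive intervals to the BED dialect
#' (0-based half-open). Overlapping intervals are written verbatim, never
#' merged.
#'
#' @param intervals data.frame with columns `chrom, start, end` (1-based
#'   inclusive) and optionally `label`.
#' @param path File path.
#' @export
write_intervals_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) && any(intervals$end < intervals$start))
    stop("interval end < start", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#coords: 0-based half-open (BED)", con)
  if (nrow(intervals)) {
    lab <- if ("label" %in% names(intervals)) intervals$label else "."
    writeLines(paste(intervals$chrom, intervals$start - 1L, intervals$end,
                     lab, sep = "\t"), con)
  }
  invisible(path)
}

#' Write / read a genetic map
#'
#' Emits two files: `<path>` with one row per bin (group, bin id, cumulative
#' cM, number of SNPs, scaffold span) and `<path>.summary.tsv` with per-group
#' totals (bins, cM length, SNPs) plus a Total row whose columns equal the
#' column sums. Refuses to write maps whose cumulative cM decreases within a
#' group.
#'
#' @param map A `genetic_map` (see [order_bins()] / [build_genetic_map()]).
#' @param path Output path for the per-bin table.
#' @return `read_genetic_map` returns a `genetic_map`.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  b <- map$bins
  for (g in unique(b$group)) {
    cm <- b$cm[b$group == g]
    if (is.unsorted(cm)) stop("cumulative cM decreases in group ", g, call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#coords: 1-based inclusive", con)
  writeLines("group\tbin\tcm\tn_snps\tscaffold\tstart\tend", con)
  writeLines(paste(b$group, b$bin, format(b$cm, trim = TRUE, digits = 10),
                   b$n_snps, b$scaffold, b$start, b$end, sep = "\t"), con)
  sm <- map_summary(map)
  write.table(sm, paste0(path, ".summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_genetic_map
#' @export
read_genetic_map <- function(path) {
  b <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  build_genetic_map(b)
}

#' Assemble a genetic map object from a per-bin table
#'
#' @param bins data.frame with columns `group, bin, cm, n_snps, scaffold,
#'   start, end` ordered by map position within group.
#' @return A `genetic_map`.
#' @export
build_genetic_map <- function(bins) {
  need <- c("group", "bin", "cm", "n_snps", "scaffold", "start", "end")
  stopifnot(all(need %in% names(bins)))
  structure(list(bins = bins), class = "genetic_map")
}

#' Per-group summary of a genetic map (bin counts, cM, SNP totals)
#'
#' @param map A `genetic_map`.
#' @return data.frame with one row per group plus a Total row.
#' @export
map_summary <- function(map) {
  b <- map$bins
  groups <- unique(b$group)
  rows <- lapply(groups, function(g) {
    x <- b[b$group == g, ]
    data.frame(group = g, n_bins = nrow(x), cm = max(x$cm) - min(x$cm),
               n_snps = sum(x$n_snps), stringsAsFactors = FALSE)
  })
  sm <- do.call(rbind, rows)
  rbind(sm, data.frame(group = "Total", n_bins = sum(sm$n_bins),
                       cm = sum(sm$cm), n_snps = sum(sm$n_snps)))
}

#' @export
print.genetic_map <- function(x, ...) {
  sm <- map_summary(x)
  n <- nrow(sm) - 1L
  cat(sprintf("genetic_map: %d group(s), %d bins, %.1f cM, %d SNPs\n",
              n, sm$n_bins[n + 1], sm$cm[n + 1], sm$n_snps[n + 1]))
  invisible(x)
}

#' Read / write a genotype matrix
#'
#' Sites x individuals matrix with codes A (homozygous parent 1), B
#' (homozygous parent 2), H (heterozygous) and `-` for missing. Row names are
#' `scaffold:pos`.
#'
#' @param gm Character matrix with values in `c("A","B","H", NA)`.
#' @param path File path.
#' @return `read_genotype_matrix` returns the character matrix (NA for `-`).
#' @export
write_genotype_matrix <- function(gm, path) {
  out <- gm
  out[is.na(out)] <- "-"
  df <- data.frame(site = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$site
  m[m == "-"] <- NA
  m
}

#' Write / read SNP tables
#'
#' VCF-like table of interspecific SNPs: `scaffold, pos, p1, p2, class` where
#' `p1`/`p2` are comma-joined parental allele sets and class is one of
#' simple / hemi / complex.
#'
#' @param snps data.frame as produced by [derive_interspecific_snps()].
#' @param path File path.
#' @export
write_snp_table <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#coords: 1-based inclusive", con)
  writeLines("scaffold\tpos\tp1\tp2\tclass", con)
  if (nrow(snps))
    writeLines(paste(snps$scaffold, snps$pos, snps$p1, snps$p2, snps$class,
                     sep = "\t"), con)
  invisible(path)
}

#' @rdname write_snp_table
#' @export
read_snp_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Minimal FASTA I/O for synthetic scaffolds
#'
#' @param seqs Named character vector of sequences.
#' @param path File path.
#' @param width Line width for writing.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  idx <- grep("^>", lines)
  if (!length(idx)) stop_parse(path, 1L, "no FASTA records")
  nm <- sub("^>\\s*", "", lines[idx])
  nm <- sub("\\s.*$", "", nm)
  ends <- c(idx[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(idx), function(i) {
    paste0(lines[seq(idx[i] + 1L, ends[i])], collapse = "")
  }, character(1))
  names(seqs) <- nm
  seqs
}

#' Write an AGP v2.1 pseudomolecule layout
#'
#' @param layout data.frame with columns `object, part, type, id, comp_start,
#'   comp_end, orientation, gap_len` (gap rows have `type == "N"`).
#' @param path File path.
#' @export
write_agp <- function(layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version 2.1", con)
  pos <- setNames(rep(0L, length(unique(layout$object))), unique(layout$object))
  part <- setNames(rep(0L, length(pos)), names(pos))
  for (i in seq_len(nrow(layout))) {
    r <- layout[i, ]
    part[r$object] <- part[r$object] + 1L
    if (r$type == "N") {
      beg <- pos[r$object] + 1L; end <- pos[r$object] + r$gap_len
      writeLines(paste(r$object, beg, end, part[r$object], "N", r$gap_len,
                       "scaffold", "yes", "map", sep = "\t"), con)
    } else {
      len <- r$comp_end - r$comp_start + 1L
      beg <- pos[r$object] + 1L; end <- pos[r$object] + len
      writeLines(paste(r$object, beg, end, part[r$object], "W", r$id,
                       r$comp_start, r$comp_end, r$orientation, sep = "\t"), con)
    }
    pos[r$object] <- if (r$type == "N") pos[r$object] + r$gap_len else
      pos[r$object] + (r$comp_end - r$comp_start + 1L)
  }
  invisible(path)
}
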