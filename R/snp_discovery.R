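# Interspecific SNP discovery from parental allele counts: per-parent site
# calling under depth/read/fraction thresholds, then classification of
# differing allele-set pairs into simple / hemi / complex.

#' Call the passing alleles at one parental site
#'
#' An allele is reported when the site depth is at least `min_depth` (default
#' 10), the allele has at least `min_allele_reads` supporting reads (default
#' 3), and it represents at least `min_allele_frac` of all reads observed
#' (default 20%). A site below the depth floor yields no call.
#'
#' @param counts Named numeric vector of read counts per allele (A,C,G,T).
#' @param min_depth,min_allele_reads,min_allele_frac Thresholds.
#' @return Character vector of passing alleles (possibly empty), with
#'   attribute `depth`.
#' @export
call_parental_site <- function(counts, min_depth = 10, min_allele_reads = 3,
                               min_allele_frac = 0.20) {
  stopifnot(all(counts >= 0))
  depth <- sum(counts)
  if (depth < min_depth) return(structure(character(0), depth = depth))
  pass <- counts >= min_allele_reads & counts >= min_allele_frac * depth
  structure(names(counts)[pass & counts > 0], depth = depth)
}

# vectorized parental calling over an allele_counts table; returns a list of
# allele-set strings keyed by scaffold:pos ("" = failed site)
call_parent_table <- function(tab, min_depth = 10, min_allele_reads = 3,
                              min_allele_frac = 0.20) {
  m <- as.matrix(tab[, c("nA", "nC", "nG", "nT")])
  colnames(m) <- ALLELES
  depth <- rowSums(m)
  pass <- m >= min_allele_reads & m >= min_allele_frac * depth & m > 0
  pass[depth < min_depth, ] <- FALSE
  sets <- apply(pass, 1, function(r) paste(ALLELES[r], collapse = ","))
  data.frame(scaffold = tab$scaffold, pos = tab$pos, alleles = sets,
             depth = depth, stringsAsFactors = FALSE)
}

#' Classify an interspecific SNP from the two parental allele sets
#'
#' For differing allele sets of size 1 or 2: simple when both parents show a
#' single (different) allele; hemi when exactly one parent shows two alleles
#' (a homoeolog-mixed pair); complex when both do (allelic variation sitting
#' on an inter-homoeolog variant).
#'
#' @param p1,p2 Character vectors of parental alleles (1 or 2 each).
#' @return "simple", "hemi" or "complex"; `NA` when the sets are identical.
#' @export
classify_snp <- function(p1, p2) {
  p1 <- sort(unique(p1)); p2 <- sort(unique(p2))
  if (length(p1) < 1 || length(p1) > 2 || length(p2) < 1 || length(p2) > 2)
    stop("allele sets must have 1 or 2 members", call. = FALSE)
  if (identical(p1, p2)) return(NA_character_)
  n1 <- length(p1); n2 <- length(p2)
  if (n1 == 1 && n2 == 1) "simple"
  else if (n1 == 2 && n2 == 2) "complex"
  else "hemi"
}

#' Derive interspecific SNPs from two parents' calls
#'
#' Keeps only sites called (non-empty allele set) in both parents, emits a
#' record wherever the two allele sets differ, and classifies it. Sites whose
#' parental allele set exceeds two members are dropped with a counter.
#'
#' @param p1_tab,p2_tab [allele_counts()] tables for parent 1 and parent 2.
#' @param cfg A [pbm_config()] supplying the calling thresholds.
#' @return data.frame `scaffold, pos, p1, p2, class` (allele sets
#'   comma-joined), with attribute `n_dropped_multiallelic`.
#' @export
derive_interspecific_snps <- function(p1_tab, p2_tab, cfg = pbm_config()) {
  c1 <- call_parent_table(p1_tab, cfg$parent_min_depth,
                          cfg$parent_min_allele_reads, cfg$parent_min_allele_frac)
  c2 <- call_parent_table(p2_tab, cfg$parent_min_depth,
                          cfg$parent_min_allele_reads, cfg$parent_min_allele_frac)
  if (!length(intersect(unique(c1$scaffold), unique(c2$scaffold))))
    stop("no shared scaffold names between parents", call. = FALSE)
  k1 <- paste0(c1$scaffold, ":", c1$pos)
  k2 <- paste0(c2$scaffold, ":", c2$pos)
  common <- intersect(k1[nzchar(c1$alleles)], k2[nzchar(c2$alleles)])
  i1 <- match(common, k1); i2 <- match(common, k2)
  a1 <- strsplit(c1$alleles[i1], ",", fixed = TRUE)
  a2 <- strsplit(c2$alleles[i2], ",", fixed = TRUE)
  len1 <- lengths(a1); len2 <- lengths(a2)
  ok <- len1 <= 2 & len2 <= 2
  dropped <- sum(!ok)
  differ <- ok & c1$alleles[i1] != c2$alleles[i2]
  cls <- rep(NA_character_, length(common))
  sel <- which(differ)
  n1 <- len1[sel]; n2 <- len2[sel]
  cls[sel] <- ifelse(n1 == 1 & n2 == 1, "simple",
                     ifelse(n1 == 2 & n2 == 2, "complex", "hemi"))
  out <- data.frame(scaffold = c1$scaffold[i1][sel], pos = c1$pos[i1][sel],
                    p1 = c1$alleles[i1][sel], p2 = c2$alleles[i2][sel],
                    class = cls[sel], stringsAsFactors = FALSE)
  out <- out[order(out$scaffold, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_multiallelic") <- dropped
  out
}

#' Retain the simple SNPs for map construction
#'
#' Hemi and complex SNPs are set aside (they mix homoeologous sequence and are
#' not usable as codominant markers at low coverage); a class-count summary is
#' attached.
#'
#' @param snps SNP table from [derive_interspecific_snps()].
#' @return The simple-SNP subset, with attribute `summary` (per-class counts
#'   and the simple fraction in percent).
#' @export
filter_for_mapping <- function(snps) {
  counts <- table(factor(snps$class, levels = c("simple", "hemi", "complex")))
  out <- snps[snps$class == "simple", , drop = FALSE]
  if (!nrow(out)) warning("no simple SNPs retained")
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    counts = as.list(counts),
    simple_fraction_pct = if (nrow(snps)) percent_of(counts[["simple"]],
                                                     nrow(snps)) else NA_real_)
  out
}
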