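#' Default pipeline configuration
#'
#' All tunable thresholds of the pipeline in one flat list, each with the
#' default used throughout: parental calling (depth >= 10, >= 3 reads per
#' allele, >= 20% allele fraction), initial F2 calls (depth >= 4, >= 1 read per
#' allele), block similarity threshold 0.7, window depth floor 40, sequencing
#' error rates E1 = 0.058 / E2 = 0.02, linkage grouping (r < 0.4, LOD >= 6),
#' mis-assembly detection (201-bp segments, >= 10 consecutive, 5 cM
#' intra-group jump), anchoring length floor 500 kb, landscape thresholds
#' (1.0 cM/Mb suppression cutoff, 50-kb SNP windows, >= 20 low windows),
#' centromere hit filters (>= 80% identity, <= 1e-20 e-value, >= 5 hits), and
#' synteny chaining (>= 10 anchors, gap 3).
#'
#' @param ... Named overrides of any default.
#' @return A list of class `pbm_config`.
#' @examples
#' cfg <- pbm_config(n_individuals = 30)
#' cfg$window_min_depth
#' @export
pbm_config <- function(...) {
  cfg <- list(
    genome_size_gb   = 2.5,
    seed             = 1L,
    # simulator stated world
    n_individuals    = 59L,
    n_chromosomes    = 2L,
    chrom_length_bp  = 2e6,
    chrom_length_cM  = c(150, 120),
    snp_per_bp       = 1 / 500,
    hemi_fraction    = 0.22,
    depth_mean       = 5.3,
    parent_depth_mean = c(61.9, 39.1),
    scaffolds_per_chrom = 8L,
    # error model
    E1 = 0.058,
    E2 = 0.02,
    # parental site calling
    parent_min_depth = 10L,
    parent_min_allele_reads = 3L,
    parent_min_allele_frac  = 0.20,
    # initial genotype calls
    init_min_depth = 4L,
    init_min_allele_reads = 1L,
    # block + window genotyping
    block_similarity = 0.7,
    window_min_depth = 40L,
    priors = c(P1P1 = 0.25, P2P2 = 0.25, P1P2 = 0.5),
    # linkage
    rf_max  = 0.4,
    lod_min = 6,
    # mis-assembly / anchoring
    segment_bp   = 201L,
    min_run      = 10L,
    cm_jump_tol  = 5,
    anchor_min_len = 5e5,
    agp_gap_bp   = 100L,
    orient_min_rho = 0.5,
    # landscape
    suppression_rate = 1.0,
    snp_window_bp    = 5e4,
    poor_min_run     = 20L,
    poor_frac_of_median = 0.1,
    # centromere
    hit_min_identity = 80,
    hit_max_evalue   = 1e-20,
    centromere_min_hits = 5L,
    # comparative
    synteny_min_anchors = 10L,
    synteny_max_gap     = 3L,
    anchor_flank_bp     = 1e4
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = "pbm_config")
}

#' Read / write a pipeline configuration
#'
#' JSON serialization of [pbm_config()]; the round trip is lossless.
#'
#' @param cfg A `pbm_config`.
#' @param path File path.
#' @return `read_config` returns a `pbm_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pbm_config"))
  raw <- unclass(cfg)
  raw$priors <- as.list(raw$priors)  # keep genotype names in the JSON object
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$priors)) raw$priors <- unlist(raw$priors)
  ints <- c("seed", "n_individuals", "n_chromosomes", "scaffolds_per_chrom",
            "parent_min_depth", "parent_min_allele_reads", "init_min_depth",
            "init_min_allele_reads", "window_min_depth", "segment_bp",
            "min_run", "agp_gap_bp", "poor_min_run", "centromere_min_hits",
            "synteny_min_anchors", "synteny_max_gap")
  for (f in intersect(ints, names(raw))) raw[[f]] <- as.integer(raw[[f]])
  do.call(pbm_config, raw)
}
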