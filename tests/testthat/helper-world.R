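# shared fixtures: small simulated worlds, memoized per seed so multiple test
# files can reuse them without re-simulating

.world_cache <- new.env(parent = emptyenv())

tiny_cfg <- function(...) {
  pbm_config(n_individuals = 24L, chrom_length_bp = 4e5,
             chrom_length_cM = c(60, 50), scaffolds_per_chrom = 4L, ...)
}

tiny_world <- function(seed = 42) {
  key <- paste0("w", seed)
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- simulate_f2(tiny_cfg(), seed = seed)
  .world_cache[[key]]
}

random_allele_counts <- function(n = 20, seed = 1) {
  set.seed(seed)
  sc <- sort(sample(c("s1", "s2"), n, replace = TRUE))
  pos <- unlist(tapply(seq_len(n), sc, function(i)
    sort(sample.int(10000, length(i)))))
  allele_counts(sc, pos, matrix(rpois(n * 4, 3), n, 4), sample_id = "rand")
}
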