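#' @useDynLib polybinmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cmdscale cor median optimize pbinom ppois qbinom rbinom
#'   rnorm rpois runif t.test setNames
#' @importFrom utils read.table write.table
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fold coverage from total sequence yield
#'
#' Converts a sequencing yield in gigabases into fold coverage of a genome of
#' known size, rounded to the reporting precision conventional for sequencing
#' summaries (one decimal).
#'
#' @param total_gb Total high-quality sequence in Gb (may be a per-individual
#'   share, see `n_individuals`).
#' @param genome_gb Genome size in Gb.
#' @param n_individuals Number of individuals the yield is split across
#'   (default 1).
#' @param digits Decimals to round to (default 1).
#' @return Fold coverage (numeric scalar).
#' @examples
#' coverage_fold(154.7, 2.5)        # 61.9
#' coverage_fold(784, 2.5, 59)      # 5.3
#' @export
coverage_fold <- function(total_gb, genome_gb, n_individuals = 1, digits = 1) {
  stopifnot(total_gb >= 0, genome_gb > 0, n_individuals >= 1)
  round(total_gb / n_individuals / genome_gb, digits)
}

#' Percentage of a total
#'
#' @param part,whole Numerator and denominator.
#' @param digits Decimals to round to (default 2).
#' @return `100 * part / whole`, rounded.
#' @examples
#' percent_of(27, 37)  # 72.97
#' @export
percent_of <- function(part, whole, digits = 2) {
  stopifnot(whole > 0)
  round(100 * part / whole, digits)
}

# deterministic child seed derivation: fixed offsets from one master seed,
# kept well below .Machine$integer.max
child_seed <- function(seed, stage) {
  offsets <- c(parents = 11L, meiosis = 23L, reads = 37L, chimera = 53L,
               hits = 71L, misc = 97L)
  stopifnot(stage %in% names(offsets))
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

stop_parse <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}
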