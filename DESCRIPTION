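Package: polybinmap
Title: Ultra-Dense Recombination Bin Maps for Allopolyploid F2 Populations
Version: 0.1.0
Authors@R:
    person("Map", "Builder", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sequence-based genotyping and ultra-dense bin-map analysis for
    interspecific F2 populations of allopolyploids genotyped at low coverage.
    Provides interspecific SNP discovery and classification (simple, hemi,
    complex), a two-step genotyper combining similarity-score block
    partitioning with sliding-window Bayesian genotype inference under
    parent-specific sequencing-error rates, recombination-bin map construction
    with EM recombination-fraction estimation and Kosambi distances, scaffold
    mis-assembly detection and anchoring into pseudomolecules, recombination
    landscape classification, SNP-density scans, centromere localization from
    filtered retrotransposon homology hits, and comparative detection of
    translocations and inversions against a diploid reference. A synthetic F2
    data generator with simulated meiosis provides a fully controlled test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
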