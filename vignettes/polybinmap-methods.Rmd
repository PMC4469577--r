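---
title: "Methods: two-step genotyping and ultra-dense bin maps for allopolyploid F2 populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-step genotyping and ultra-dense bin maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polybinmap)
```

## The problem

An interspecific F2 population of an allotetraploid crop (two subgenomes, A
and D) is sequenced at low coverage (~5x) together with its two inbred
parents (sequenced deeply). The goal is an ultra-dense genetic map: millions
of interspecific SNPs collapsed into recombination bins, ordered into
linkage groups, and used to audit and anchor a fragmented genome assembly,
to profile the recombination landscape, and to localize centromeric regions
from retrotransposon homology.

Two features make the allopolyploid setting hard. First, homoeologous
sequence: short reads from the sister subgenome alias onto a locus and
produce apparent "alleles" that do not segregate. Second, low per-site
coverage: with ~5 reads per site a heterozygote is routinely miscalled as a
homozygote (one allele simply not sampled), and many sites are missing
outright.

## SNP discovery and classification

Each parent's allele counts are screened per site: depth at least 10, an
allele needs at least 3 supporting reads and at least 20% of all reads.
Sites called in both parents with differing allele sets become
interspecific SNPs and fall into three classes:

* **simple** — one clean allele per parent, alleles differ;
* **hemi** — one parent shows a two-allele mixture (its locus plus a
  homoeologous copy), the other a single allele;
* **complex** — both parents show mixtures.

Only simple SNPs are used for mapping; hemi and complex sites mix
homoeologs and are not reliable codominant markers at low coverage. The
classification is implemented as allele-set arithmetic on counts (the
package never sees alignments); the two alignment-level scenarios that both
produce a "simple" pattern are intentionally collapsed, since they are
indistinguishable from counts.

## Two-step genotyping

**Step 1 — initial calls and blocks.** Per site and individual, informative
reads (those carrying either parental allele) are thresholded: depth < 4 is
missing; otherwise only-parent-1 reads give A, only-parent-2 B, both H.
These calls are noisy on purpose — they only feed the block partition. A
similarity score between two sites' genotype vectors averages, over
individuals scored in both, s = 1 (identical), 0.5 (one is H), 0
(A vs B). Sites are agglomerated left-to-right along a scaffold into blocks:
a site joins while its score against the block's running consensus
(per-individual majority) is at least 0.7. Blocks exist to stop information
from flowing across chimeric junctions inside mis-assembled scaffolds: a
junction flips the genotype pattern and forces a new block.

**Step 2 — sliding-window Bayesian calls.** Within a block, a window grows
symmetrically around each focal site over consecutive sites until it holds
at least 40 informative reads (an exhausted block below 40 leaves the site
missing). With n pooled reads of which n1 carry the parent-1 allele, and
parent-specific per-read error rates E1 = 0.058 and E2 = 0.02,

* P(n1 | P1P1) = C(n, n1) (1 - E1)^n1 E2^(n - n1)
* P(n1 | P2P2) = C(n, n1) E1^n1 (1 - E2)^(n - n1)
* P(n1 | P1P2) = C(n, n1) p^n1 (1 - p)^(n - n1), p = (1 - E1 + E2) / 2

with F2 priors 1/4 : 1/4 : 1/2; the call is the maximum posterior, exact
ties are left missing. Two notational choices are deliberate: the binomial
coefficient is read as C(n, n1) in all three expressions, and the
heterozygote probability carries the per-read 1/2 normalization — without
it the "likelihood" is not a probability and the heterozygote is
systematically over-called. All computation is in log space; posteriors are
renormalized, so any common factor is irrelevant to the call.

The window geometry (symmetric growth, preferring the nearer site and the
left side on index ties) and the depth-adaptive (rather than fixed-width)
window are package contracts; only the 40-read floor is externally fixed.

## Bins, linkage, and the map

Sites with complete, identical genotype vectors across the population form
a recombination bin (sites with any residual missing call are set aside;
they can still ride along for anchoring via their nearest bin, but never
define one). Pairwise recombination fractions between bin representative
vectors are estimated by EM for two codominant F2 loci over the nine
genotype-pair classes; the double heterozygote is a coupling/repulsion
mixture handled in the E step (initialization r = 0.25, tolerance 1e-8, cap
200 iterations — the estimate is deterministic). LOD is the base-10
likelihood ratio against r = 0.5.

Grouping is single-linkage over edges with r < 0.4 and LOD >= 6. Ordering
within a group starts from two deterministic seeds — the first principal
coordinate of the Kosambi distance matrix, and a greedy nearest-neighbour
chain from the most peripheral bin — and refines both by alternating 2-opt
reversals with or-opt relocations of 1-3 bins, keeping the order with the
smaller sum of adjacent r. The two seeds cover each other's failure mode:
the PCoA embedding can fold when most pairwise distances saturate near
r = 0.5 (long chromosomes), while greedy chaining is locally myopic.
Cumulative positions are Kosambi distances, d = 25 ln((1+2r)/(1-2r)) cM, of
adjacent fractions; orientation of a finished group is fixed by requiring
the first bin's index not to exceed the last's. A quality matrix (pairwise
similarity above the diagonal, 1 - 2r below) makes order defects visible as
off-diagonal hot spots.

## Mis-assembly detection and anchoring

Every mapped SNP deep enough inside its scaffold yields a 201-bp segment
(100 bp each side). Segments without a unique full-length match on the
assembly are dropped (on synthetic data the flags are exact-search results
supplied by the caller; on real data they come from an upstream aligner).
Runs of at least 10 consecutive segments in the same bin are "stable". A
breakpoint is called between adjacent stable runs that disagree: always
when their linkage groups differ; within a group, when the cM sequence from
the left run through any intervening short-bin segments to the right run
jumps by more than 5 cM somewhere (a smooth staircase of short bins is not
a breakpoint — that is what a recombination-dense region looks like). When
a bin-level recombination matrix is supplied, an intra-group candidate must
also be corroborated by the direct Kosambi distance between the two
flanking bins exceeding the same tolerance; this suppresses artifacts from
cumulative-cM noise and from a genotype pattern recurring at a second
nearby location (double crossovers can restore a pattern). Breakpoints sit
at the midpoint of the largest offending step and are classified
homoeologous (A/D partners of one index), interchromosomal, or
intrachromosomal.

Split pieces are assigned their runs' group, ordered by median cM, oriented
by the sign of the Spearman correlation of cM against scaffold coordinate
(|rho| >= 0.5, else flagged), placed only above a length floor (default
500 kb), and emitted as AGP with fixed 100-bp gaps.

## Landscape and centromeres

Per adjacent-bin interval, rate = cM span / Mb span; below 1.0 cM/Mb is a
suppression segment, at or above it a hotspot (the boundary value is a
hotspot, since "less than 1.0" defines suppression). SNP density is counted
in 50-kb windows; at least 20 consecutive windows below the low threshold
(default: 10% of the genome-wide median window count, stamped into output)
merge into a SNP-poor region.

Centromeres: homology hits are filtered at >= 80% identity and <= 1e-20
e-value, pooled per chromosome (optionally per query), and summarized by
the median hit midpoint with its distribution-free 95% confidence interval
from order statistics — ranks qbinom(0.025, n, 1/2) and n + 1 minus that
(at n = 25: ranks 8-18). The order-statistic method was chosen over a
bootstrap for determinism; the source phrase "median size of the 95%
confidence interval for the median" is read as "the median and its 95% CI".
Chromosomes with fewer than 5 filtered hits are reported as having no
detectable centromeric region rather than a degenerate interval. Subgenome
contrasts use Welch's t-test on per-chromosome hit counts (the variant is a
package choice); when both subgenomes have identical constant counts the
contrast degenerates and is reported as t = 0, p = 1.

## Comparative stage

Synteny anchors (one best reference location each) are chained within a
linkage group into blocks on a single reference chromosome with a
consistent direction, tolerating up to 3 consecutive discordant anchors as
outliers; blocks need at least 10 anchors. Calls: a reciprocal
translocation is the exchange pattern (two groups each holding a large
block homing to the other's chromosome — one symmetric call per pair); a
lone foreign block is a simple translocation; a minority-orientation block
among same-chromosome blocks of its group is an inversion. Interval sizes
are (end - start)/1e6 Mb to two decimals — the plain coordinate difference,
which is what printed interval sizes in the field match.

## The synthetic world

The generator states one fixed world; its defaults are not tuned to tests.

* 59 F2 individuals at 5.3x mean depth, E1 = 0.058, E2 = 0.02 — the
  population scale and error structure of the motivating study.
* SNP density 1 per 500 bp, Poisson-spaced; hemi fraction 0.22 (the hemi
  share of all interspecific SNPs in the motivating study is ~22%).
* Test scale: 2 chromosomes x 2 Mb, 8 scaffolds each, 150 and 120 cM, so a
  full pipeline run takes seconds. Genetic lengths are kept at
  chromosome-realistic values rather than scaled with the (shortened)
  physical length; the price is that bins carry ~20 SNPs instead of
  thousands, which is exactly why the mis-assembly rule needs the
  bridged-staircase refinement described above.
* Meiosis is Poisson without interference (crossover count ~ cM/100,
  uniform positions, random phase); Kosambi is used downstream purely as a
  distance transform. Reads are binomial draws per site: parent-1-allele
  probability 1 - E1 (truth A), E1 (truth B), (1 - E1 + E2)/2 (truth H);
  hemi sites add a contaminating stream at the locus depth. Centromere hits
  are truncated normals around the true centromere plus uniform background
  straddling the filter thresholds.
* One master seed; stage seeds are fixed offsets of it, so a world is
  byte-reproducible from its config.

What the generator does **not** emulate: alignment and mapping-quality
artifacts, indels and structural variants other than injected chimeras,
segregation distortion, crossover interference, depth heterogeneity along
the genome, and the real asymmetry behind E1 != E2 (the rates are free
parameters here). A green test therefore establishes correctness of the
algorithms under the stated generative model, not robustness to upstream
alignment pathology.

## Numerical and design choices worth knowing

* Internal coordinates are 1-based inclusive throughout (the R convention);
  conversion to 0-based half-open happens only in the BED writer. Each
  tabular output states its dialect in a header comment.
* Configuration is JSON (jsonlite), not YAML, with a lossless round trip.
* Posterior ties and all-missing similarity scores are treated
  conservatively (missing / non-linkable), never broken arbitrarily.
* Consensus ties in block building resolve A before H before B,
  deterministically.
* The EM recombination estimator is clipped to [0, 0.5]; Kosambi inputs are
  clipped to 0.4999 only where a saturated estimate must still yield a
  finite distance (seeding, adjacent-gap accumulation).
* `build_bins` partitions globally by exact vector equality, so a pattern
  recurring at two locations forms one (non-contiguous) bin; downstream
  consumers that care about contiguity (mis-assembly detection) corroborate
  with direct recombination evidence instead of assuming it.
* Map-recovery checks run the linkage stage on the simulator's true
  genotype matrix; genotyping noise is assessed separately by the two-step
  improvement checks. This isolates failures to one stage.

## Known limitations

* Ordering is heuristic (seeded local search); for pathological
  recombination-fraction matrices the optimum found may differ from the
  global one, though the exhaustive-enumeration oracle bounds this on small
  instances.
* The intra-group breakpoint tolerance (5 cM) and the SNP-poor "low"
  threshold (10% of median) are package contracts with no external source;
  both are config and stamped into outputs.
* `estimate_rf_f2` assumes codominant F2 data; dominant markers and
  distorted segregation are out of scope.
* The CLI holds whole matrices in memory; at the motivating study's true
  scale (millions of SNPs) the per-scaffold stages would need chunking.
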