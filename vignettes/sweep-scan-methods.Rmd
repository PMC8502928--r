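---
title: "Haplotype-based sweep scans with neutral coalescent calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based sweep scans with neutral coalescent calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Recent positive selection leaves a characteristic footprint in phased
genotype data: as an adaptive allele rises in frequency it drags a long,
unbroken haplotype with it, so chromosomes carrying the selected allele are
unusually homozygous over an extended region. `sweepscan` detects this
footprint on the human X chromosome (or any phased locus) with three
statistics built on extended haplotype homozygosity (EHH), calibrates them
against neutral coalescent simulations under an explicit demographic model,
and feeds the resulting candidate regions into two downstream enrichment
analyses: X-inactivation (XCI) escape genes and enhancer-like regulatory
elements.

The X chromosome needs its own machinery.  Its effective population size is
three quarters of the autosomal one, males are hemizygous, and the
pseudoautosomal regions recombine with the Y, so the scan works on the
non-pseudoautosomal region only and the neutral expectation comes from an
X-specific three-population demographic model.

## Data model

A `haplotype_matrix` is the substrate of every statistic: an `n_hap` by
`n_snp` binary matrix with 0 for the ancestral and 1 for the derived allele
(polarization against an outgroup-informed ancestral-allele table happens at
VCF ingestion; sites with unknown ancestral state, or whose ancestral allele
matches neither REF nor ALT, are dropped).  Physical positions are strictly
increasing bp; genetic positions in cM come from linear interpolation of a
recombination map, clamped to the terminal anchors so chromosome ends still
receive genetic coordinates.  Diploid-phased samples contribute two
haplotypes, haploid male X samples one.  Unphased genotypes are a hard
error: every statistic here is meaningless on unphased data.

## The statistics

For a core SNP, `EHH(x)` is the probability that two chromosomes drawn at
random from a carrier class are identical at every SNP between the core and
position `x`.  With haplotype classes of sizes $n_h$ among $n$ carriers,

$$\mathrm{EHH} = \frac{\sum_h \binom{n_h}{2}}{\binom{n}{2}}.$$

Curves are extended site by site in both directions and stop when EHH drops
below the truncation value (default 0.05).  The integrated haplotype
homozygosity iHH is the trapezoidal integral of the curve against genetic
distance, cut at the interpolated crossing of the truncation threshold so
that the area below the cutoff never contributes.

* **iHS** = $\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$, the log-ratio of the
  ancestral- and derived-allele integrals.  Under this sign convention an
  unusually long *derived* haplotype gives a *negative* unstandardized
  score; the statistic is two-sided after standardization.  (Some scanners
  print the reciprocal ratio; only the sign flips.)
* **nSL** replaces genetic distance with segregating-site counts (one unit
  per site), making it independent of the recombination map and more
  sensitive to soft sweeps.
* **iHH12** integrates EHH12, the variant in which all haplotypes form the
  carrier set and the two most frequent haplotype classes are pooled:
  $\mathrm{EHH12} = [\binom{n_1+n_2}{2} + \sum_{h\ge3}\binom{n_h}{2}]/\binom{n}{2}$.
  Pooling the top two classes makes it sensitive to both hard and soft
  sweeps.  It is one-sided: large positive values are the signal.

Unstandardized scores depend strongly on the derived allele frequency
(DAF), so each statistic is z-scored within 100 equal-width DAF bins,
separately per population.  The bin variance uses denominator *n*
(definitional z-scoring of the observed distribution).  A `reference` score
table can supply the bin moments — the analogue of normalizing against the
pooled genome rather than a single locus — and the calibration and power
machinery uses the pooled neutral tables for exactly this reason: a locus
enriched in extreme scores must not deflate its own z-scores.

### Failure modes, not missing-data fudges

A core site is scored only if every one of its four (iHS/nSL) or two
(iHH12) EHH curves terminates cleanly.  Three things invalidate a curve:

* **gap** — an inter-SNP gap above 20 kb before truncation; large gaps
  create spuriously long homozygous stretches;
* **edge** — the chromosome (or simulated locus) ends while EHH is still
  above the truncation value, so the integral would be censored;
* **few carriers** — fewer than two chromosomes in an allele class.

On 600-kb simulated loci roughly half the iHS sites fail at the edge; this
mirrors the behavior of the standard scanners on short contigs and is the
reason the simulated calibration loci are windowed identically to real
data rather than compared site-by-site.  A maximum extension (1 Mb
physical for the map-based statistics, 200 sites for nSL) truncates a
curve without invalidating it.

## Windowing and calibration

Per-SNP scores are averaged in 20-kb windows sliding by 16 kb (20%
overlap): mean $|z|$ for the two-sided iHS and nSL, raw mean $z$ for
iHH12.  Windows with 20 SNPs or fewer are removed — single-SNP outliers do
not make a sweep.  Because no analytic null exists for these window means,
critical values are empirical quantiles (99th and 99.9th, linear
interpolation) of window means computed from neutral coalescent replicates
processed through the identical pipeline, pooled across replicates.
Candidate calling is strict (`>`): a window exactly at the threshold is not
a candidate.  No p-values are attached to windows; the thresholds are
percentile cut-offs, not tests.

Per-population swept regions are the union of 99th-percentile candidate
windows over the three statistics with overlapping windows merged
(bookended regions stay separate).  Regions overlapping by at least 1 bp
across populations merge into shared regions classified as `unique`,
`continental`, or `cross-continental`.

## The neutral simulator

The calibration engine is a structured coalescent with recombination
written in C++ against the ms parameter conventions: time in units of
$4N_{\mathrm{ref}}$ generations, deme sizes relative to
$N_{\mathrm{ref}}$, exponential growth per $4N$ units, migration entries
$4N m$, and locus-wide $\theta = 4N\mu L$ and $\rho = 4NrL$ (always derived
from per-generation rates, never set directly).  Ancestral material is
tracked per lineage as segments carrying descendant bit sets; segments
that reach their local MRCA retire, mutations fall on lineages as an
infinite-sites Poisson process, and recombination splits lineages at a
uniform breakpoint within their ancestral span.  Every batch is a pure
function of `(model, n_reps, seed)`.

The preset `x_chromosome_model()` encodes the three-population X model:
$N_{\mathrm{ref}} = 10{,}538.25$ (the 3/4-scaled autosomal reference),
sample sizes 152/153/149 chromosomes (AFR/EUR/ASI), present relative sizes
2.204/3.2542/7.4055, growth 56.61 and 96 per $4N$ units in EUR and ASI,
symmetric migration 0.3542/0.1462/1.3562, the ASI–EUR merger at
$t = 0.0464$ (EUR size to 0.2939, AFR–EUR migration to 4.9314), the
EUR–AFR merger at $t = 0.14022$, and the ancestral size change at
$t = 0.364$.  With $\mu = 1.25\times10^{-8}$, $r = 1.3\times10^{-8}$ and
$L = 600$ kb this gives $\theta = 316.1475$ and $\rho = 328.7934$.  Note
two bookkeeping subtleties: the pooled ASI sample size used by the
simulation command (149) differs from the rounded arithmetic mean of the
five East-Asian population counts (153) — the preset follows the
simulation command, `pooled_sample_sizes()` reports the means — and the
value 328.79 sometimes quoted as $\theta$ is actually $\rho$; both
constants are recomputed from first principles here, not copied.

The simulator is validated against closed forms in its single-deme
constant-size reduction: mean segregating sites against Watterson's
$\theta\sum 1/i$ and the unfolded site frequency spectrum against the
$1/i$ shape.  The SFS check uses per-class z-tests on replicate means
(replicates are independent; sites within a replicate share a genealogy
and are not), Bonferroni-corrected — a pooled-count chi-square would be
anti-conservative.

### Sweep injection

`inject_sweep()` is a haplotype-copy device, not a selection simulation:
one donor haplotype is copied onto recipients within a span around a core
site until the core derived frequency reaches `round(f*n)/n`.  It creates
exactly the homozygosity structure the statistics target, deterministically
— sufficient for power analysis, and honest about what it is.  The core is
the nearest polymorphic site whose frequency does not already exceed the
target.  A side effect worth knowing: copying purges variation inside the
span, so sites there often drop below the MAF filter and the window
containing the core itself can fall under the 21-SNP minimum.  Detection
is therefore assessed on windows overlapping the injected span, where the
flanking shoulder of the signal lives — the same reasoning applies to real
sweeps.

## Enrichment analyses

*XCI escape.*  Genes overlapped (≥ 1 bp) by candidate windows are
"selected"; a 2×2 table of XCI status (escape/inactive; `variable`
excluded by default) against selection status is assessed by Fisher's
exact test, computed definitionally as the sum of hypergeometric
probabilities no larger than the observed table's.  The odds ratio is the
sample cross-product $(ad)/(bc)$, reported as 0/∞ for zero cells with no
continuity correction; degenerate margins (e.g. every gene selected)
return p = 1 rather than an error.

*SNP prioritization.*  A SNP is retained when its |z| lies in the top 1%
for at least one statistic *and* its PHRED-scaled deleteriousness score is
at least 10 (inclusive), the conventional 1%-most-deleterious cutoff.
SNPs without a deleteriousness annotation are excluded and counted.

*Regulatory overlap.*  Candidate windows are partitioned into genic
(fully covered by gene spans), intergenic, and partial; prioritized SNPs
are compared against a background set through overlap proportions with
functional elements and the derived odds ratios.

*Consensus enhancers.*  Cell-type-specific enhancer records targeting the
same gene are collapsed when their intervals overlap or when the 20-kb/16-kb
scan-grid windows they cover are contiguous; the merged record spans
(min start, max end), takes the union of cell lines and the maximum
database support.  The construction is idempotent and per-gene disjoint.
The window grid used for "contiguous" is configurable; the scan grid is the
natural default since enhancer–window overlap drives the selection calls.
Association between enhancer selection and target-gene selection is a
Pearson chi-squared without continuity correction (the data tables here
are large; a warning recommends the exact test when an expected cell drops
below 1), with observed-vs-expected cells and mean enhancer–gene distances
per cell as linkage diagnostics.

## Synthetic annotation fixtures

`annotation_fixtures()` generates the gene/XCI/enhancer/SNP tables with a
*planted* ground truth: escape genes are selected at a configurable odds
ratio ω against a baseline selection probability (default 0.15), with the
59-escape/381-inactive universe as default; enhancers expand into 1–3
jittered cell-line records; a configurable set of SNPs passes both
prioritization filters.  Everything is a deterministic function of
`(config, seed)`.  What these fixtures emulate is the *contingency
structure* of the real annotation data, not its spatial statistics: gene
placement is near-uniform, enhancer–gene distances are draws, and
selection status is planted per gene rather than arising from haplotype
scores.  Tests against fixtures therefore validate estimator calibration
and recovery (type-I error, power, odds-ratio bias), and say nothing about
LD between neighbouring genes in real data.

## Numerical and design choices

* Coordinates: VCF input (1-based) converts to 0-based half-open
  internally; all BED output is 0-based half-open.  Interval overlap means
  ≥ 1 bp under half-open semantics everywhere, so bookended intervals never
  touch.
* Duplicate-position SNPs keep the first record (with a warning); ancestral
  mismatches are dropped, never strand-flipped.
* Quantiles use the linear-interpolation estimator (R type 7).
* EHH truncation 0.05, gap 20 kb, MAF filter strictly greater than 5%,
  100 DAF bins, 20-kb/16-kb windows with the >20-SNP rule — all exposed in
  `scan_params()` / `default_config()` and recorded in every run's output.
* Ties at thresholds are non-candidates (strict `>`): extreme-tail
  semantics, and ties have probability zero for continuous scores.

## Problem sizes

The package's own test and reproduction runs use desk-scale sizes chosen to
keep the statistics stable: 30 neutral 600-kb replicates (≈ 1,100 pooled
windows) for threshold calibration, 12 replicates for sweep power at
derived frequency 0.8, 2,000 replicates of the 10-chromosome constant-size
model for the closed-form simulator checks, and 200–300 fixture seeds for
the enrichment calibration.  A full-scale calibration (254 replicates, as
in the preset's provenance) runs the identical code path.

## Known limitations

* The simulator is infinite-sites on a continuous locus mapped to integer
  bp; rare position collisions drop the later mutation.
* `nSL` follows the common scanner implementation (unit distance per site
  within the scored SNP set) rather than the original per-pair
  segregating-site normalization.
* Sweep injection is not a forward simulation; allele-frequency
  trajectories and age structure of real sweeps are out of scope.
* The enhancer consensus rule inherits the ambiguity of "contiguous
  windows" from its source convention; the scan grid default is a choice,
  exposed as a parameter.
* No p-values for windows by design; the percentile calibration is the
  inferential device.
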