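# sweepscan

Detection of recent positive selection from phased haplotypes, built for
X-chromosome scans: per-SNP EHH statistics (iHS, nSL, iHH12) with
frequency-bin standardization, windowed candidate calling calibrated
against neutral coalescent simulations under a three-population X
demographic model, cross-population sweep sharing, and downstream
enrichment analyses for X-inactivation escape genes and enhancer-like
regulatory elements.

It is aimed at population geneticists who want a selection scan whose
every constant — polarization rules, MAF and gap filters, window geometry,
percentile cut-offs, demographic parameters — lives in one auditable
configuration, with the neutral calibration data generated by code in the
same package.

## What it computes

For a core SNP, extended haplotype homozygosity at distance *x* is the
probability that two randomly chosen carrier chromosomes are identical
over the whole interval: EHH = Σ<sub>h</sub> C(n<sub>h</sub>,2) / C(n,2)
over haplotype classes of sizes n<sub>h</sub>. Curves are integrated
(trapezoid, truncated at EHH = 0.05) to iHH, and:

* **iHS** = ln(iHH<sub>A</sub>/iHH<sub>D</sub>) — incomplete hard sweeps;
  long derived haplotypes give negative unstandardized values;
* **nSL** — the same ratio with distance counted in segregating sites,
  map-free and sensitive to soft sweeps;
* **iHH12** — integrated EHH with the two most frequent haplotype classes
  pooled, EHH12 = [C(n₁+n₂,2) + Σ<sub>h≥3</sub> C(n<sub>h</sub>,2)]/C(n,2),
  sensitive to both hard and soft sweeps.

Scores are z-scored within 100 derived-allele-frequency bins, averaged in
20-kb windows sliding by 16 kb (windows with ≤ 20 SNPs removed), and
windows exceeding the 99th / 99.9th percentile of neutral-simulation
window means are called candidates. A structured coalescent with
recombination (C++, ms parameter conventions) generates the neutral
replicates; the preset model is the three-deme X-chromosome history with
θ = 316.1475 and ρ = 328.7934 over 600 kb. Windowed Tajima's D, sweep
injection for power analysis, Fisher/chi-squared enrichment machinery and
synthetic annotation fixtures with planted ground truth round out the
pipeline.

## Worked example

Simulate one neutral 600-kb replicate under the X model, score the African
deme, and summarize windows:

```r
library(sweepscan)

model <- x_chromosome_model()
model
#> demographic_model: 3 deme(s), n_ref = 10538.2
#>   samples: AFR=152, EUR=153, ASI=149 (total 454 chromosomes)
#>   locus: 600,000 bp, theta = 316.1475, rho = 328.7934
#>   6 demographic event(s), last at t = 0.364

batch <- simulate_neutral(model, 1, seed = 1)
afr <- maf_filter(subset_haplotypes(batch$replicates[[1]],
                                    haplotypes = "AFR",
                                    drop_monomorphic = TRUE), 0.05)
afr
#> haplotype_matrix: 152 haplotypes x 1373 SNPs on sim
#>   span: 301-599,653 bp (0.0004-0.7795 cM)
#>   populations: AFR (152)

scores <- standardize_scores(site_scores(afr))
head(scores[!is.na(scores$ihs_std),
            c("pos", "daf", "ihs_unstd", "ihs_std", "nsl_std", "ihh12_std")], 4)
#>       pos       daf   ihs_unstd    ihs_std    nsl_std   ihh12_std
#> 95  45789 0.5723684 -0.01535817 -0.4077999 -0.1047196 -0.98068240
#> 97  45979 0.4276316 -0.14724539  0.6754365  0.3842850 -0.06510621
#> 98  46372 0.4276316 -0.14724539  0.6754365  0.3842850 -0.06510621
#> 100 46752 0.4276316 -0.05290142  0.9443305  0.3152553  0.20533400

windows <- summarize_windows(make_windows(c(0, model$L)), scores)
head(windows[, c("start", "end", "snp_count", "mean_ihs", "mean_ihh12")], 3)
#>   start   end snp_count  mean_ihs  mean_ihh12
#> 1     0 20000        39        NA          NA
#> 2 16000 36000        45        NA -0.13724219
#> 3 32000 52000        30 0.6757509  0.06838416
```

Each scored row is one SNP: `ihs_unstd` is the raw log-ratio of ancestral
to derived integrated EHH and `ihs_std` its z-score within the SNP's
derived-allele-frequency bin, so values beyond roughly ±2.5 are
chromosome-wide outliers. Window means near 0 are the neutral
expectation; candidate windows are those whose means exceed the 99th
percentile of window means from many such neutral replicates
(`neutral_thresholds()` + `call_candidates()`). The `NA` means in the
first windows are honest: EHH curves that hit the locus edge before
decaying below truncation invalidate their core sites, so edge windows
often carry no scored iHS values.

`run_scan(demo_config())` drives the same machinery end to end — neutral
calibration, candidate calling, sweep sharing across the three demes, and
the enrichment analyses on planted annotation fixtures — writing score
tables, window BEDs, threshold sidecars and a run manifest into the
output directory.

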