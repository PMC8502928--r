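Package: sweepscan
Title: Haplotype-Based Selective Sweep Scans with Coalescent Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of recent positive selection on the human X chromosome
    (and other phased loci) from extended haplotype homozygosity (EHH)
    statistics: per-SNP iHS, nSL and iHH12 with frequency-bin standardization,
    windowed Tajima's D, sliding-window candidate calling calibrated against
    neutral coalescent simulations, and cross-population sweep sharing.
    Includes an ms-parameterized structured coalescent simulator with
    recombination, migration, growth and demographic events (with a preset
    three-population X-chromosome model), sweep injection for power analysis,
    and downstream enrichment analyses for X-inactivation escape genes and
    enhancer-like regulatory elements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    vcfR,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
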