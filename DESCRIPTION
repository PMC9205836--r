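Package: pulsegs
Title: Stochastic Simulation of Genomic Selection in Pulse Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stochastic simulator of inbred (self-pollinating) pulse crop
    breeding programs for comparing phenotypic selection against genomic
    selection strategies. Simulates a multi-trait, multi-environment QTL
    architecture on a seven-chromosome genetic map, meiosis with Poisson
    recombination and mutation, single seed descent, ridge-regression
    (SNP-BLUP) marker effect estimation and genomic breeding values,
    optimal-haploid-value selection of primary crosses and F1 intercrosses
    with in-silico progeny projection, truncation and selection-index based
    stage selection, genomic-relationship and allele-fixation diversity
    metrics, and a genetic-algorithm parent selector that penalizes
    relatedness and allele fixation. Breeding scenarios differ in bulk-up
    method (field or glasshouse single seed descent) and in the stage at
    which parents are recycled to the germplasm pool (Stage 2, F6, F2, F1),
    and are compared on annual genetic gain and genetic-diversity loss.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
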