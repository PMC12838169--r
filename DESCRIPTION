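Package: ihsscan
Title: Selection Scans on Phased Haplotype Panels via the Integrated
    Haplotype Score
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for whole-genome scans for recent positive selection in
    small resequenced populations. Implements extended haplotype
    homozygosity (EHH) curves, integrated haplotype homozygosity (iHH) with
    0.05 truncation, the unstandardized and derived-allele-frequency-bin
    standardized integrated haplotype score (iHS), and candidate-region
    extraction with gene-model annotation. Ships the supporting machinery a
    resequencing study needs around the scan: caller-side and scan-level SNP
    quality control (depth, mapping quality, SNP spacing, indel proximity,
    missingness, minor allele frequency, an exact Hardy-Weinberg test),
    per-individual variant summaries (transition/transversion ratios,
    zygosity, annotation tallies), identity-by-state distances, observed and
    expected heterozygosity, polymorphism information content, inbreeding
    coefficients, runs of homozygosity, and linkage-disequilibrium decay
    curves. A forward-in-time diploid Wright-Fisher simulator with optional
    additive selective sweeps generates phased panels with known ancestral
    alleles so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
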