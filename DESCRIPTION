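Package: rnadx
Title: Cohort-Based RNA-Seq Outlier Diagnostics for Rare Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and prioritization of transcriptional aberrations in
    whole-blood RNA-seq cohorts for rare-disease diagnostics. Implements
    cohort-based gene-expression outlier detection (negative-binomial tail
    tests with PCA confounder removal), a junction coverage-score screen for
    aberrant splicing, an overdispersion-aware beta-binomial test for
    allele-specific expression at rare heterozygous sites, gene-dosage
    summaries over copy-number variants, and phenotype (HPO) driven candidate
    ranking. Includes a synthetic-cohort generator with planted aberrations
    and a truth ledger for benchmarking sensitivity and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
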