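Package: cnvcc
Title: Case-Control Burden, Association and Familial Overlap Analysis of
    Copy-Number Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for rare copy-number variant (CNV) segment
    calls in case-control cohorts and small pedigrees: per-cohort sample
    quality control by a segment-count cutoff, sex-stratified size-binned
    CNV burden testing with one-sided exact tests and Bonferroni
    correction, breakpoint pseudo-marker construction with one-sided
    permutation-based case-control association, sweep-line detection of
    CNV regions shared among affected family members, and interval
    annotation of loci against gene lists. Includes a seeded synthetic
    cohort and pedigree simulator with planted ground truth so every
    analysis is exercisable and reproducible without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
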