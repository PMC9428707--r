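Package: reoPairs
Title: Reversal Gene-Pair Discovery and Rank-Based Diagnostic
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery of diagnostic biomarkers built from within-sample
    relative expression orderings (REO) of gene pairs. Implements
    detection of group-consistent gene pairs at a configurable
    consistency threshold, reversal pairs between disease and
    non-disease groups, the reversal-degree statistic (geometric mean of
    group-wise mean absolute rank differences), forward selection of a
    gene-pair panel under a half-voting rule, rank-invariant sample
    classification, performance evaluation (sensitivity, specificity,
    geometric mean, stratified accuracy, Fisher's exact reversal test),
    and a synthetic-cohort generator with planted reversal structure,
    monotone platform distortions and multi-platform views for
    end-to-end validation. Includes expression-matrix preprocessing:
    probe-to-gene collapse, counts-to-FPKM conversion and gene-universe
    intersection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
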