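Package: plasmaCNA
Title: Copy-Number Abnormality Scoring and Histology Classification for
    Shallow-WGS Liquid Biopsies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for somatic copy-number analysis of cell-free DNA from
    shallow whole-genome sequencing. Starting from bin-wise (100 kb)
    normalized log2-ratio profiles and a healthy reference panel, the
    package segments profiles by a circular-binary-segmentation-style
    search, computes reference-standardized segmental Z-scores, calls
    gains and losses at |Z| >= 3, summarises tumor burden with the
    segment-length-weighted CPA (copy number profile abnormality) score,
    calibrates a 1%-FDR abnormality cutoff from control CPA scores,
    classifies histological subtype (LUAD/LUSC/SCLC) from discretized
    per-bin copy-number states with ridge-penalized multinomial logistic
    regression, quantifies paired solid/liquid concordance, and models
    in-silico tumor enrichment by cfDNA insert-size filtering. A fully
    seeded synthetic-cohort generator provides reference panels,
    subtype-fingerprinted cases, array-style training tables and
    fragment-size-annotated reads for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    glmnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    nortest,
    pROC,
    randomForest,
    e1071,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
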