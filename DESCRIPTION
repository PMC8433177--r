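Package: fibroscope
Title: Cell-Type Deconvolution, Morphometric Scoring and Gene Signatures
    for Liver Fibrosis Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for staging liver fibrosis from bulk
    transcriptomes and histology-derived morphometry. Provides a seeded
    synthetic-data generator for stage-structured cohorts (single-cell
    reference, negative-binomial bulk mixtures, tile-level morphometric
    features); a continuous per-sample fibrosis score from tile features
    via repeated down-sampling, PCA and cross-validated support-vector
    regression; cross-subject-consistency-weighted non-negative
    least-squares deconvolution of bulk samples against a multi-subject
    single-cell reference with pseudo-bulk benchmarking; cell-type-specific
    differential expression by proportion-interaction regression; and
    fibrosis gene signatures from per-gene proportional-odds models,
    coefficient-of-variation ranking, composite sample scores and lasso
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    e1071,
    glmnet,
    jsonlite,
    methods,
    pracma,
    stats,
    tools,
    utils
Suggests:
    MASS,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
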