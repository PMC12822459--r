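Package: tlscape
Title: TLS Detection and Immune Signature Analysis for Treatment-Response
    Single-Cell and Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a reusable pipeline for tumor-microenvironment
    analysis of neoadjuvant chemoradiotherapy cohorts: MAD-based single-cell
    quality control and log-normalization, gene-signature scoring (module
    scores with expression-matched control genes, and summed scores),
    derivation of a treatment-associated tertiary lymphoid structure (TLS)
    signature, bimodal-pseudotime staging of exhausted T cells, percentile
    threshold calibration and TLS region calling in binned spatial
    transcriptomics with ROC/AUC validation, and the accompanying group-level
    statistics. Ships a synthetic-data generator with planted ground truth
    that emulates the statistical assumptions of every stage, so the whole
    pipeline is testable end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
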