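Package: serosig
Title: Serum Inflammatory Proteome Signatures and Patient Subgroup Discovery
Version: 0.1.0
Authors@R: person("Serosig", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for multiplex serum protein panels measured on
    the NPX (normalized protein expression, log2-like) scale, as produced by
    proximity extension assays. Provides detection-rate quality filtering,
    nonparametric differential abundance with two-stage
    Benjamini-Krieger-Yekutieli false discovery rate control, confounder
    stratified re-testing, fixed-specificity k-of-n multi-marker panel
    classification with logistic-regression marker subset selection,
    differential co-expression via residual Spearman correlation matrices
    with Ward clustering, and patient subgroup discovery calibrated against
    a random-cluster permutation null. Includes a synthetic cohort generator
    with planted effects, group-specific correlation blocks and
    limit-of-detection censoring, so every stage can be validated against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
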