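Package: altsig
Title: Tumor-Cell Annotation and CD83 Signature Analysis for Glioma
    Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies malignant cells in single-cell RNA-seq by combining a
    per-marker two-component Gaussian mixture classifier with copy-number and
    single-nucleotide-variant evidence, derives a CD83-positive tumor-cell gene
    signature from a gain-of-function versus wild-type comparison, and scores,
    refines (iterative single-sample gene set enrichment with correlation
    pruning), correlates and survival-stratifies that signature in single-cell,
    pseudobulk and bulk cohorts. Ships a synthetic-cohort generator that
    emulates the statistical structure of every input so the full pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    survival,
    utils
Suggests:
    DESeq2,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
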