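Package: immunoscope
Title: Signature-Based Immune Cell Enrichment Analysis for Bulk Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimates the relative enrichment of immune cell types in bulk
    tissue transcriptomes from cell-type gene signatures. Implements quantile
    normalization, two-sample gene set enrichment analysis (weighted
    Kolmogorov-Smirnov running sum with a phenotype-permutation null and
    normalized enrichment scores), single-sample enrichment scoring (ssGSEA),
    median-signature treatment-response prediction with ROC/AUC, and
    signature correlation analysis with common-gene removal. Ships a
    synthetic bulk-mixture generator with known cell-type fractions so that
    every stage of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    limma,
    pROC,
    withr
Config/testthat/edition: 3
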