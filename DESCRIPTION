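Package: targetscreen
Title: Screening and Cross-Validated Classification of Omic Features of
    Drug-Target Clinical Success
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for finding gene and protein features that separate
    clinically successful drug targets from targets that failed in late-stage
    trials. Implements net phase III outcome scoring from asset-level records,
    kind-aware standardization of gene-by-feature matrices with row-summary and
    expression-entropy features, correlation-based dimensionality reduction,
    permutation tests for outcome association with optional within-class
    stratification and Benjamini-Yekutieli false discovery rate control,
    bootstrap replication-probability analyses (plain, class-holdout, and
    within-class-permutation schemes), a nested cross-validation classifier
    with incremental feature elimination, and evaluation utilities including
    performance percentiles, predicted-probability densities, predictive-value
    cutoff scans, and pairwise target-ranking consistency. A synthetic-data
    generator with planted outcome effects and confounded target classes makes
    every stage testable without proprietary clinical-outcome data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
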