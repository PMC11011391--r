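Package: survomics
Title: Multiomics Feature Extraction and Survival Classification for Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature engineering and evaluation pipeline for dichotomized
    (2-year) survival prediction from multiomics tumor data. Extracts
    features from sparse somatic-mutation and copy-number data (SBS96,
    DBS78 and ID83 mutation catalogues, reference-signature exposures,
    gene-level and gene-set aggregation, multi-sample region-overlap
    partitioning of copy-number segments), normalizes count matrices with
    the median-of-ratios estimator, profiles per-omics feature value with
    L1-penalized logistic regression, ranks features with a shadow-feature
    (Boruta-style) random-forest procedure, and evaluates classifiers
    under class-balanced nested cross-validation with Monte-Carlo Shapley
    attribution. Includes a synthetic multiomics cohort generator with
    planted survival signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    randomForest,
    pracma,
    Biostrings,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
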