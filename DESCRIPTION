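Package: urimir
Title: Urinary miRNA Biomarker Discovery and Validation Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end workflow for discovering and validating urinary
    microRNA biomarkers of bladder cancer subtypes from small RNA-seq read
    counts and qPCR Ct values. Implements median-of-ratios depth
    normalization, permutation-calibrated surrogate-variable estimation for
    unwanted variation, negative-binomial Wald differential expression with
    moment/trend dispersion shrinkage, single-miRNA predictive-power scoring
    by leave-one-out logistic classification, stability-based endogenous
    control selection from sequencing counts, delta-delta-Ct qPCR statistics
    with covariate-adjusted association and ordered-subtype trend tests, and
    paired ROC comparison of risk-factor models with and without a miRNA
    panel (DeLong test). A negative-binomial cohort simulator with planted
    fold changes, housekeeping miRNAs, batch effects and linked Ct values
    makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    DESeq2,
    SummarizedExperiment
Config/testthat/edition: 3
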