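Package: omistrat
Title: Multi-Omics Stratification of Septic Shock Patients by Longitudinal
    Ratio Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies severe septic shock patients by 28-day mortality from
    the day-7 over day-1 variation of targeted metabolomics, iTRAQ proteomics
    and continuous clinical variables. Implements the full analysis chain:
    quality-control filters for targeted metabolite panels (missingness and
    limit-of-detection rules), LOESS intensity normalization for multi-batch
    iTRAQ proteomics, per-patient D7/D1 ratio construction, rank-based
    univariate screening with false discovery rate control, cascaded
    minimum-redundancy maximum-relevance (mRMR) feature ranking across omics
    layers, and three classifier families on the top-ranked features:
    elastic-net logistic regression with two minimal-deviance selection
    strategies, linear discriminant analysis, and partial least squares
    discriminant analysis with weighted centering and variable importance in
    projection (VIP) scores. A synthetic-cohort generator with planted
    group effects, block-correlated features, censoring and batch structure
    makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
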