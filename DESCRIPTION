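Package: nichekit
Title: Ensemble Species Distribution Modelling and Niche-Dynamics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for invasion-risk assessment with ensemble
    species distribution models. Covers occurrence cleaning and grid thinning,
    pseudo-absence sampling, collinearity filtering, eight single-model
    families (ANN, CTA, FDA, GBM, GLM, MaxEnt-style penalized
    presence-background regression, RF, SRE) under one fit/predict contract,
    AUC and true-skill-statistic evaluation with TSS-maximizing binarization,
    top-k ensemble construction on a 0-1000 suitability scale, scenario
    projection with spherical area accounting and centroid-shift analysis, and
    niche-dynamics quantification in a two-axis environmental PCA space
    (Schoener's D overlap, expansion/stability/unfilling, equivalency and
    similarity permutation tests, predicted niche occupancy profiles). A
    virtual-species simulator with known ground truth supports validation of
    the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    MASS,
    nnet,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    geosphere,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
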