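Package: habitatMSI
Title: Intratumoral Habitat Clustering and Multi-Regional Spatial
    Interaction Analysis for CT Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Density-based subregion (habitat) discovery in CT lung nodules
    and quantification of intratumoral spatial heterogeneity through the
    Multi-regional Spatial Interaction (MSI) matrix. Provides SLIC-style 3D
    supervoxel oversegmentation, cohort-level Gaussian-mixture clustering of
    supervoxel phenotypes with elbow-based model selection, MSI co-occurrence
    matrices with 33 first-order and 5 second-order features, and a complete
    grade-prediction harness: SMOTE rebalancing, RFE + LASSO feature
    selection, a preprocessor-by-classifier model grid, ROC/AUC with DeLong
    comparisons, calibration and Brier scores, decision-curve analysis, exact
    Shapley attributions, tumor-size subgroup evaluation, and a seeded
    synthetic nodule-cohort generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    mclust,
    glmnet,
    MASS,
    randomForest,
    e1071,
    rpart
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
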