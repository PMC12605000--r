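Package: habitrad
Title: Habitat-Based MRI Radiomics for Binary Molecular Label Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Entropy-based intratumoral habitat partitioning and subregion
    radiomics for predicting a binary molecular label (such as EGFR T790M
    status) from multi-sequence MRI of spinal metastases. Implements local
    entropy maps, patient-level superpixelization, population-level Ward
    clustering with data-driven cluster counts, subregion texture feature
    extraction (GLCM, GLDM, GLSZM, first order, image filters), ICC
    reproducibility filtering, parametric empirical-Bayes ComBat batch
    harmonization with a train-fit/apply split, leakage-safe Mann-Whitney +
    LASSO signature construction inside nested cross-validation,
    multi-sequence regional fusion modeling, full discrimination,
    calibration and decision-curve evaluation, and closed-form Shapley
    attributions for the linear models. A synthetic lesion cohort generator
    with known habitat structure, class effects and scanner batch effects
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    cluster,
    sva
Config/testthat/edition: 3
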