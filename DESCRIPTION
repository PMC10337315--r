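Package: petrad
Title: PET Radiomics Model Validation and Extension for Residual
    Oesophageal Tumour Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for externally validating and extending 18F-FDG
    PET radiomic prediction models of residual oesophageal cancer after
    neoadjuvant chemoradiotherapy. Provides a synthetic multi-scanner
    PET cohort generator, SUV conversion with serum-glucose correction,
    isotropic resampling and grey-level discretisation, IBSI-style
    radiomic features (intensity statistics, histogram, GLCM, GLRLM,
    GLSZM, morphology), external-validation metrics (AUC with bootstrap
    confidence intervals, calibration slope and intercept, operating
    points at fixed sensitivity), per-scanner feature harmonisation,
    bootstrapped LASSO model extension with optimism-corrected AUC, a
    stratified-subsampling classifier benchmark, and cohort-comparison
    statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    MASS,
    purrr,
    randomForest,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
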