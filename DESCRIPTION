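Package: dosiomics
Title: Dosiomic and Radiomic NTCP Modeling of Radiation-Induced Xerostomia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normal tissue complication probability (NTCP) modeling of
    radiation-induced xerostomia from three-dimensional dose distributions
    and parotid gland geometry. Provides voxel-grid handling (isotropic
    resampling, contour rasterization, sagittal-flip lateralization into
    ipsi- and contralateral glands), extraction of radiomic shape features,
    dose-volume histogram statistics, subvolume mean doses, spatial dose
    gradients and normalized central dose moments, a Kendall-tau redundancy
    filter, a rank-based univariate screen (Mann-Whitney AUC with BCa
    bootstrap confidence intervals, adaptive false-discovery-rate step-down
    control, logistic tolerance doses), a configurable multivariate
    model-building pipeline (class-imbalance samplers, feature selectors,
    seven classifiers, random-search tuning under Monte Carlo or
    leave-pair-out cross-validation, nested cross-validation), rank-based
    algorithm comparison (Friedman, Nemenyi, Holm-Bonferroni), and a
    synthetic cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    ranger,
    e1071,
    xgboost,
    RNifti,
    jsonlite,
    yaml
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
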