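Package: radiomlp
Title: Radiomic Features and MLP Ensembles for Brain Tumor MRI Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for distinguishing glioblastoma from primary
    central nervous system lymphoma (PCNSL) on MRI: seeded synthetic phantom
    cohorts (contrast-enhanced T1-weighted and diffusion-weighted volumes with
    class-dependent enhancement, texture and diffusivity), preprocessing
    (masked intensity normalization, two-point ADC mapping, outlier clipping,
    isotropic resampling), threshold/region-growing segmentation, a 936-feature
    radiomic engine (first-order, GLCM and GLRLM texture over 13 directions,
    single-level Haar wavelet sub-bands), three feature-selection methods
    (mRMR, CFS, backward elimination), three classifiers (RBF SVM,
    componentwise GLM boosting, importance-regularized random forest), a
    class-weighted multilayer-perceptron ensemble with majority voting, and
    evaluation via AUC, Youden thresholds and relative-standard-deviation
    stability, including an internal versus protocol-shifted external
    validation design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    e1071,
    ranger,
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
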