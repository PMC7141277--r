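Package: gqidl
Title: Generalized Q-Sampling Index Maps, Volumetric Autoencoder Features,
    and Imbalance-Aware Classification for Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying group differences in multi-shell diffusion
    MRI with model-free generalized q-sampling reconstruction. Provides a
    synthetic cohort simulator (multi-tensor forward model with Rician
    noise and configurable regional group effects), generalized q-sampling
    reconstruction of orientation distribution functions with GFA, ISO, QA
    and NQA scalar maps, a self-contained 3D convolutional autoencoder for
    unsupervised compression of index maps into subject-level feature
    vectors, and an imbalance-aware classification protocol (stratified
    half-splits, 4:1:1 partitioning with 5-fold cross-validation, iterated
    gradient-boosted trees and logistic regression, ROC/AUC reporting).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    xgboost,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
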