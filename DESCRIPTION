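Package: ADStage
Title: Severity Staging of Alzheimer's Disease from Imaging-Derived Features
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for staging Alzheimer's disease severity
    from imaging-derived morphometric features. Provides a variational
    volumetric denoiser with candidate-filter local search and PSNR
    evaluation, a robust multitask feature-learning solver (row-sparse
    shared weights plus column-sparse outlier tasks under l2,1 penalties),
    principal-component reduction with a cumulative explained-variance
    stopping rule, Mini-Mental State Examination (MMSE) severity banding,
    baseline classifiers (KNN, SVM, decision tree, LDA, random forest) and a
    small one-dimensional convolutional network, together with
    confusion-matrix, sensitivity/precision and one-vs-rest ROC/AUC
    reporting. Seeded synthetic generators emulate the study data shapes
    (noisy phantom volumes, multitask regression problems with planted
    supports, class-conditional patient cohorts) so the whole pipeline is
    testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    MASS,
    rpart,
    e1071,
    randomForest,
    caret,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'volume.R'
    'synthetic-phantom.R'
    'mmse.R'
    'synthetic-cohort.R'
    'synthetic-multitask.R'
    'denoise.R'
    'rmtfl.R'
    'reduction.R'
    'classifiers.R'
    'cnn.R'
    'evaluation.R'
    'pipeline.R'
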