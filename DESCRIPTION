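Package: kinfate
Title: Predicting Single-Cell Division Events from Kinase Activity Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting whether an individual cell will divide from
    its ERK and Akt kinase-activity time courses, as measured by live-cell
    reporters (cytoplasmic-to-nuclear ratio of a kinase translocation
    reporter). Provides a synthetic cohort generator with class-dependent
    low-frequency trends and AR(1) noise, class-artifact-free preprocessing
    (length-distribution matching and mean padding), low-frequency feature
    extraction via the Haar discrete wavelet transform and discrete Fourier
    amplitudes, multi-modal heterogeneous stacking ensembles with
    nested-cross-validation stacker selection, minority-class F-max
    evaluation with threshold transfer, and a permutation-based
    interpretation algorithm that maps model importance back to time.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    glmnet,
    ranger,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
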