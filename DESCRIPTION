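Package: hjortheeg
Title: Band-Wise Hjorth Parameters and Subject-Independent EEG Group
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for screening two groups of subjects (e.g. a
    patient cohort against healthy controls) from resting-state
    multi-channel EEG. Continuous recordings are resampled, band-pass
    filtered with zero-phase FIR filters, re-referenced to the common
    average, decomposed into the five canonical sub-bands (delta, theta,
    alpha, beta, gamma) and cut into fixed-length epochs. Hjorth
    parameters (activity, mobility, complexity) are computed per epoch,
    channel and band; features are reduced by greedy
    maximum-relevance/minimum-redundancy (mRMR) selection and evaluated
    with leave-one-subject-out cross-validation over pluggable
    classifiers (linear SVM, LDA, k-nearest neighbours, random forest),
    with pooled accuracy/sensitivity/specificity, ROC/AUC, exact
    per-subject binomial tests against chance, channel-wise Wilcoxon
    rank-sum statistics, and LIME surrogate explanations aggregated into
    per-channel scalp importance maps. A seeded synthetic-cohort
    generator with controllable band-limited group effects makes every
    stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    MASS,
    class,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
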