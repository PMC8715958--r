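Package: petriage
Title: Diagnosing Conflicting Memory-Test Cases from FDG-PET with a Compact 3D Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for triaging memory-impairment cohorts whose three
    neuropsychological memory tests (MMSE-Recall, ADAS-Cog-Recall, CDR-Memory)
    conflict, training a compact 3D convolutional classifier on FDG-PET SUVr
    volumes of concordant ("certain") cases, and diagnosing the discordant
    ("uncertain") cases. Includes a synthetic cohort and phantom-volume
    generator with a geometric region atlas, pons-reference SUVr
    normalisation and Gaussian smoothing, a fivefold cross-validation
    harness with classification metrics and ROC/AUC, baseline classifiers,
    PCA/t-SNE embeddings of network features, longitudinal decline
    validation (6-month binned group tests, OLS trends with confidence
    intervals, within-subject stability), voxelwise and region-of-interest
    group statistics with Bonferroni/Benjamini-Hochberg control and
    cluster-extent filtering, a geriatric depression scale item battery,
    and a balanced repeated-subsampling two-way ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    e1071,
    nnet,
    RNifti,
    jsonlite,
    readr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
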