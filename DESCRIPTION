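Package: noduletex
Title: 2D CT Radiomics of Part-Solid Lung Nodules with Repeated-CV LASSO
    Selection and Reader-Study Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Texture-feature radiomics pipeline for 2D CT cross-sections of
    segmented lung nodules. Provides a synthetic part-solid ground-glass
    nodule cohort generator, a semi-automatic segmentation surrogate
    (rectangle seed, bimodal threshold, largest component, hole filling),
    61 radiomic features across first-order, gray-level co-occurrence,
    run-length, size-zone and neighborhood gray-tone-difference families,
    feature-importance selection by L1-penalized logistic regression under
    ten repeats of stratified tenfold cross-validation, Youden-index
    cutoffs with univariate and stepwise multivariable logistic modelling,
    and paired reader-study statistics (McNemar tests, paired-difference
    confidence intervals, DeLong AUC comparison). Minimal NIfTI-1 I/O and
    a JSON-configured command-line pipeline are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
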