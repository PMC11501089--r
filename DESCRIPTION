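Package: intune
Title: Individualized Neural Tuning Models via Warp Hyperalignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates individualized neural tuning (INT) models of
    fine-grained cortical functional organization from multi-subject
    stimulus-locked response time series.  A group functional template is
    built with a searchlight PCA-Procrustes algorithm, each participant's
    data are modeled as a linearly transformed template using warp
    hyperalignment (searchlight ensembles of bagged ridge regressions),
    and the modeled responses are decomposed into a shared orthogonal
    stimulus matrix and participant-specific tuning matrices.  Includes
    prediction of individualized category-selectivity and phase-encoded
    retinotopic maps, movie time-point classification, reliability and
    distinctiveness metrics, and a synthetic-cohort generator for
    validating every stage without real neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    xml2,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
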