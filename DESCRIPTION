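Package: bhmnet
Title: Bayesian Joint Estimation of Low- and High-Order Brain Functional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates brain functional networks from region-of-interest
    (ROI) rs-fMRI time series. Implements the classical low-order estimators
    (Pearson's correlation, shrunk Pearson's correlation, sparse
    representation via L1-regularised regression, Laplacian-prior soft
    thresholding), the high-order correlation's-correlation network, and a
    Bayesian high-order model (BHM) that jointly estimates the low-order
    edge-weight matrix W and its high-order covariance network Omega under a
    matrix-variate normal prior, solved by alternating optimisation. Includes
    a synthetic-cohort generator with planted group-discriminative edges, an
    edge-feature classification pipeline (two-sample t-test selection, linear
    SVM, nested leave-one-out cross-validation with accuracy, sensitivity and
    specificity reporting), delimited-text readers and writers for time
    series and networks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
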