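Package: nirselect
Title: Genetic-Algorithm Feature Selection for SVM Classification of
    Near-Infrared Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Classifies samples from near-infrared (NIR) absorbance spectra
    by Savitzky-Golay de-noising, Mahalanobis-distance outlier removal,
    principal component feature extraction, genetic-algorithm wrapper
    selection of a fixed-size principal-component subset, and a
    binary-decision-tree multiclass soft-margin support vector machine with
    a Gaussian radial basis kernel.  Includes a synthetic NIR spectra
    generator with planted class structure for end-to-end validation,
    stratified train/test splitting, grid search with k-fold
    cross-validation for the kernel parameters, and per-class evaluation
    (sensitivity, specificity, precision, F1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
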