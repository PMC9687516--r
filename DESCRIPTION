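Package: eotrhtex
Title: Entropy and GLCM Texture Analysis of Equine Dental Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the radiographic texture of equine incisor teeth for
    grading Equine Odontoclastic Tooth Resorption and Hypercementosis (EOTRH).
    Implements three preprocessing filters (normalize, median, Laplacian
    sharpening), five two-dimensional entropy measures (sample, fuzzy,
    permutation, dispersion and distribution entropy), six gray-level
    co-occurrence matrix features, grade-wise statistics with compact letter
    displays, regression-based similarity testing, and threshold-based
    detection accuracy (sensitivity, specificity, predictive values). A
    synthetic phantom generator produces graded tooth regions of interest with
    resorption and hypercementosis-like lesions so the full pipeline is
    testable without clinical radiographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    png,
    jpeg,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
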