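Package: teaorigin
Title: Geographic Origin Classification of Maojian Tea from Near-Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible chemometrics pipeline for discriminating the
    geographic origin of Maojian green tea (Changsha, Chengdu, Xinyang,
    Zunyi) from near-infrared absorbance spectra. Provides a synthetic
    spectrum generator that emulates the shared and origin-discriminating
    absorption bands of the four origins, the measurement-to-model-input
    preprocessing chain (replicate averaging, rubber-band convex-hull
    baseline correction, min-max normalization, stratified 7:3 splitting
    with a per-class validation carve-out), three classifiers -- a
    back-propagation neural network, a pooling-free one-dimensional
    AlexNet variant, and a RepSet-style permutation-invariant network
    whose features are exact maximum-weight bipartite matchings between
    the input set and trainable hidden sets -- plus confusion-matrix
    metrics (per-class precision, macro average, overall accuracy) and a
    configuration-driven command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
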