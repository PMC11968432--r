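Package: drpfuse
Title: Multi-Omics Drug-Response Prediction with Pathway-Guided Sparse PCA
    and Similarity-Network Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for predicting binary drug response of cell
    lines from multi-omics profiles. Implements waterfall binarization of
    IC50 curves, semi-supervised weighted edge sparse PCA for per-drug,
    pathway-constrained feature selection, rank-correlation sample
    similarity networks per omics, a dip-test and variance weighted fusion
    of similarity blocks (including a from-scratch Hartigan dip statistic
    with Monte-Carlo calibration), and a compact one-dimensional
    convolution plus Kolmogorov-Arnold network classifier trained by
    backpropagation. A seeded synthetic-cohort generator with planted
    pathway signal supports testing and benchmarking of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
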