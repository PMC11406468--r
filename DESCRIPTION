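Package: muellermap
Title: Multispectral Mueller-Matrix Polarimetry of Brain Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-wise analysis of multispectral Mueller-matrix image cubes
    of biological tissue: forward instrument modeling and least-squares
    reconstruction from intensity frame stacks, physical-realizability
    screening via the ensemble criterion, indices of polarimetric purity and
    anisotropy coefficients, three decompositions (Lu-Chipman forward polar,
    five-layer symmetric, and differential matrix-logarithm with fluctuation
    statistics), region statistics, and grey/white-matter classification with
    leave-one-specimen-out cross-validated k-nearest neighbors, permutation
    feature importance, and sequential floating feature selection. Includes a
    synthetic multispectral brain phantom generator so the full pipeline runs
    without any measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    tiff,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    pracma,
    withr
Config/testthat/edition: 3
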