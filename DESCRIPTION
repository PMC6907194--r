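Package: grmdim
Title: Eigenvalue Dimensionality of Genomic Relationship Matrices and GBLUP Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates structured livestock breeding populations forward in time
    (bottlenecked historical phase followed by discrete recent generations with a
    small effective population size), builds VanRaden genomic relationship matrices
    (GRM), and runs genomic BLUP with three covariance options: the full blended GRM,
    a rank-truncated GRM keeping the r largest eigenvalues, and the sparse APY
    (algorithm for proven and young) inverse. Prediction quality is quantified both
    as realized accuracy against simulated true breeding values and through
    prediction-error-variance (PEV) based approximations with effective record
    counts, including a fast reduced-rank PEV route through the GRM eigenbasis.
    Includes eigenvalue-profile diagnostics relating GRM dimensionality to the
    number of independent chromosome segments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
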