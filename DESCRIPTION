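Package: maxassoc
Title: Maximal Association Coefficient for Linear and Nonlinear Dependence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects linear and nonlinear association between two numeric
    variables with the maximal association coefficient (MAC), a
    piecewise-linear dependence measure. Each variable is discretized into
    contiguous bins by one-dimensional K-means clustering; every admissible
    s-by-t grid within a sample-size-dependent budget is scored by the
    area-weighted sum of per-cell absolute Pearson correlations, and the
    maximum over grids is reported. Includes a simulation framework
    (ten benchmark relationship types with R-squared-calibrated uniform
    vertical noise) for generality and equitability experiments, a pairwise
    screening matrix for tabular data, tidy accessors, ggplot2 plots, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
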