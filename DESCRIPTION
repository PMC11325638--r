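Package: natechdisparity
Title: Screening, Exposure Classification, and Spatial Disparity Models for
    Hurricane-Related Contaminant Releases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reusable pipeline for environmental-justice analyses of
    natural-hazard-triggered technological ("natech") contaminant releases.
    Screens excess air emissions events and land/water release reports with
    cause, source-type, and keyword filters; constructs hurricane, matched
    reference, and random-day study periods; computes daily dominant wind
    directions from gridded zonal/meridional components and classifies census
    block groups as exposed, at-risk, unexposed, or excluded by downwind
    sector and buffer proximity to releases; summarises event counts and
    released mass by period, facility type, cause, and contaminant group; and
    estimates sociodemographic disparities in exposure with a from-scratch
    Bayesian binomial Leroux conditional autoregressive (CAR) model fitted by
    Markov chain Monte Carlo, alongside a county-fixed-effect logistic
    baseline and Moran's I permutation diagnostics. A synthetic-data module
    generates region geometry, demographics, facilities, reports, wind fields,
    and model-based outcomes with known parameters so that every stage can be
    tested end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    geosphere,
    optparse,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
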