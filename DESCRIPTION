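Package: dcmair
Title: Dynamic Coregionalization Models for Country-Level Air Quality
    Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Model-based assessment of air quality over a region from an
    unbalanced, missing-data-bearing multivariate monitoring network.
    Implements the dynamic coregionalization model (a hierarchical
    space-time model combining a latent Markov temporal state, direct and
    coregionalized spatial Gaussian processes and measurement error),
    maximum-likelihood estimation by an EM algorithm built on the Kalman
    smoother, dynamic kriging maps with prediction variances, latent-state
    global air-quality indices with confidence intervals, and
    population-weighted ambient exposure and exceedance-risk indices with
    parametric-bootstrap uncertainty. A synthetic-scenario generator
    emulating a country-scale three-pollutant network supports end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
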