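Package: simcal
Title: Training Satellite Crop-State Retrievals on Crop-Model Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for calibrating an ensemble of maize crop-growth-model
    simulations against regional yields and season lengths with
    simplex-constrained least squares, and for training bidirectional
    recurrent (BLSTM) networks that retrieve in-season crop state
    variables, yields, and phenological stage probabilities from
    multispectral reflectance time series. Includes a seeded synthetic-data
    generator (weather, a surrogate daily crop simulator over a factorial
    agromanagement grid, a forward canopy reflectance model, and
    mixture-based county-year observations), weather- and geography-based
    county clustering, county-blocked k-fold cross-validation, and the
    associated evaluation metrics (explained standard deviation,
    per-timestep percentage uncertainty reduced, CDF-based phenological
    transition dates, and stage confusion/kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
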