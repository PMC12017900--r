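Package: reefscape
Title: Multiscale Reef Terrain Analysis and Presence-Background Species
    Distribution Modelling
Version: 0.1.0
Authors@R:
    person("Reefscape", "Developers", email = "reefscape@example.org",
           role = c("aut", "cre"))
Description: A transferable multiscale framework for marine species
    distribution modelling from bathymetric digital elevation models (DEMs).
    Generalises co-located bathymetry sources to nested resolutions with a
    Gaussian pyramid, derives eight topographic predictors (slope, eastness,
    northness, vertical and horizontal curvature, vector ruggedness measure,
    bathymetric position index, sky view factor) plus depth, assesses DEM
    vertical accuracy against tide-corrected field depth records (NMAD, RMSE,
    outlier screening, Q-Q data), and fits MaxEnt-style presence-background
    models (L1-penalized logistic regression over feature-class expansions)
    with leave-one-reef-out cross-validation, rank-sum parameter selection,
    jackknife variable importance, response curves and habitat-overlap
    summaries. Ships a seeded synthetic reef generator so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
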