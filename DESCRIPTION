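Package: reefscape
Title: Multi-Scale Seafloor Terrain Analysis and Fish Species Distribution Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting marine species distributions across coral
    reef seascapes from high-resolution bathymetry. Derives six terrain
    morphometrics (depth, slope, aspect, slope of slope, planar curvature,
    rugosity) from a bathymetric grid, aggregates them with circular
    focal-mean windows at multiple spatial scales, and adds Euclidean
    distance-to-shoreline and distance-to-shelf-edge surfaces as cross-shelf
    location predictors. Fits stochastic gradient boosted regression trees
    (with cross-validated tree-count selection, variable importance, partial
    dependence and interaction strength) and presence-only maximum-entropy
    models (L1-regularised Gibbs distributions with jackknife predictor
    importance), and evaluates them with cross-validated ROC AUC,
    pseudo-absence AUC and threshold-based map accuracy. Includes a synthetic
    seascape simulator with known species-response structure so the whole
    pipeline can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
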