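Package: connage
Title: Brain-Age Modelling from Multimodal Connectivity with Downstream
    Cognitive Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating brain age from multimodal neuroimaging
    derivatives and relating the resulting brain-age gap to cognition and
    psychological resilience in older adults. Builds static and
    sliding-window functional connectivity, nodal temporal variability,
    volume-scaled structural connectivity and synchronization-likelihood
    matrices from regional time series; thresholds connectivity into binary
    networks and computes nodal graph metrics; fits a two-round
    cross-validated Lasso brain-age model producing per-subject brain-age
    gaps; and provides covariate-adjusted partial correlations with false
    discovery rate control, first-pair canonical correlation analysis with
    permutation inference, cognitive-status stratification, and repeated
    k-means classification. A synthetic cohort generator with planted
    age-connectivity signal and a planted resilience-gap association makes
    the full pipeline testable without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
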