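Package: revo
Title: Weighted-Ensemble Simulation with Resampling of Ensembles by
    Variation Optimization
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Weighted-ensemble (WE) enhanced sampling for rare events,
    built around the region-free REVO resampler, which clones and merges
    trajectory walkers to maximize a pairwise-distance "trajectory
    variation" objective. Includes a reference WExplore resampler based
    on hierarchical Voronoi regions, an N-dimensional biased random-walk
    benchmark system with an analytic target distribution,
    boundary-condition warping for unbinding-flux and residence-time
    estimation, a distance-exponent calibration procedure on early/late
    walker ensembles, and post-run analysis (predicted probability
    profiles, accuracy, sampling range, run-to-run standard error,
    origin-distance statistics). Run records are persisted as JSON-lines
    and a command-line driver is provided.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, StructuralPrediction
RoxygenNote: 7.3.3
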