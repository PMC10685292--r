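Package: amsplan
Title: Superiorized Feasibility-Seeking for Linearly Constrained Inverse
    Radiotherapy Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inverse treatment planning for intensity-modulated radiation
    therapy posed as a convex feasibility problem over per-voxel dose
    hyperslabs. Implements the sequential AMS (Agmon-Motzkin-Schoenberg)
    relaxation method with per-voxel weights and nonnegativity projection,
    and its superiorized version that interlaces summable objective-reducing
    gradient perturbations into the feasibility-seeking sweeps. Ships a
    synthetic TG119-like horseshoe phantom and a physically plausible
    beamlet dose-influence model so every algorithm is testable without
    clinical data, together with dose-volume-histogram analytics, plan
    comparison, file round-trips (MatrixMarket, CSV, JSON) and a
    config-driven command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
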