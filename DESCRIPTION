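Package: bwspawn
Title: Spawning Distribution of Blue Whiting Larvae from Plankton
    Recorder Presence/Absence Records
Version: 1.0.0
Authors@R:
    person("CPR", "Modelling Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the spawning distribution and phenology of
    blue whiting (Micromesistius poutassou) from Continuous Plankton
    Recorder (CPR) presence/absence records. Implements a penalized
    regression-spline Bernoulli generalised additive model (GAM) engine
    with cyclic and tensor-product smoothers fitted by penalized
    iteratively reweighted least squares, UBRE-type smoothness selection
    with an overfit-penalty multiplier, an ensemble of ten candidate
    space-time model structures compared by AIC, and derived products:
    normalised spatial spawning densities, peak-timing maps with
    highest-density-region masks, zonally integrated latitude by
    day-of-year distributions, and annual abundance indices with
    posterior confidence intervals. Includes a synthetic CPR-like survey
    generator with a known two-component spawning truth for parameter
    recovery testing, UTM coordinate projection, and solar-elevation
    based day/night classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
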