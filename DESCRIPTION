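Package: foragesim
Title: Simulation and Analysis of Data-Foraging Strategies on a Dune Transect
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying spatial data-collection ("data foraging")
    strategies in a simulated geologic survey. Generates seeded synthetic
    moisture-strength datasets along a dune transect under two competing
    soil-saturation hypotheses, constructs and classifies sampling strategies
    by the equal-spacing and magic-number heuristics, fits the piecewise-linear
    saturation model by breakpoint grid search with an RMSE fitting error,
    executes strategies against a dataset to produce fitting-error
    trajectories, runs Monte-Carlo comparisons of heuristic versus random
    sampling designs, and classifies participant logs for anchoring,
    adaptation and conclusion errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
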