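Package: bcrwalk
Title: Biased and Correlated Random Walks for Animal Movement Analysis
Version: 0.1.0
Authors@R:
    person("Movement", "Ecology Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing GPS relocation data of sedentary animals with
    a two-dimensional biased and correlated random walk (BCR). The model mixes
    isotropic diffusion with three behavioural forces -- inertia (persistence),
    immobility and attraction toward a den -- and admits a closed-form
    estimator of the force weights from raw trajectories via quadrant counting
    of movement situations. The package provides the simulator, the estimator,
    five trajectory statistics (turning-angle distributions, kernel home-range
    isopleths, path dilation, still and mobile transect censuses) with L1 and
    relative error comparators, subsampling and sensitivity experiments, and
    Monte-Carlo alpha-shape detection of anomalous spatial voids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    grDevices,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
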