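Package: rrptools
Title: Stochastic Docking-Site Models and Readily Releasable Pool
    Estimators for Single-Synapse Vesicle Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discrete-time Monte Carlo simulators of sequential
    vesicle-docking models at presynaptic active zones (the two-slot
    replacement-site/docking-site model, the one-slot loose-state/tight-state
    model, and an intermediate-pool extension), together with the estimators
    used in quantal analyses of single-synapse vesicle-count recordings:
    docking-site counting by binomial fitting and variance-mean analysis,
    covariance profiling of successive release counts, back-extrapolation of
    cumulative release for readily-releasable-pool sizing, depression and
    latency metrics, model parameter fitting, a synthetic-data generator for
    count matrices, latency rasters and postsynaptic current traces, and a
    template-deconvolution event counter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
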