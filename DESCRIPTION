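Package: CircuitCaliber
Title: Stochastic Inference of Gene-Circuit Parameters from Single-Cell
    Expression Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates single-gene auto-activation and two-gene toggle-switch
    circuits exactly with the Gillespie stochastic simulation algorithm, and
    infers circuit parameters from frame-sampled protein-count trajectories
    with three likelihood-based engines: a detailed chemical-master-equation
    model with explicit promoter states solved by Finite State Projection, a
    coarse-grain model with Hill-function feedback, and a Maximum Caliber
    path-entropy model. Provides transition-count likelihoods over m-frame
    windows, derivative-free maximum-likelihood fitting, effective-rate
    extraction, and replicate benchmarking reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
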