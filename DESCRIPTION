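Package: mranoise
Title: Noise Propagation in Modular Response Analysis Network Reconstruction
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study how measurement noise propagates through Modular
    Response Analysis (MRA) based reconstruction of signalling networks.
    Provides two three-node ODE test-bed models (a MAPK phosphorylation
    cascade and a p53-MDM2-ATM feedback system), simulation of steady-state
    perturbation experiments, a combined multiplicative-lognormal plus
    additive-Gaussian measurement error model with replicate structure and
    two control strategies, the two MRA transformations (finite-difference
    global response coefficients and the linear-system solve for local
    response coefficients, with mean, ordinary least squares and total
    least squares estimators), robust tail statistics based on the
    medcouple, a sign-aware AUC measure of network recovery, and Monte
    Carlo orchestration over scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
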