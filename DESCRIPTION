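Package: bumpdrift
Title: Drift and Diffusion of Bump States in Ring Attractor Networks with
    Short-Term Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytical predictions and simulators for the slow dynamics of
    activity bumps in one-dimensional continuous attractor networks with
    short-term synaptic facilitation and depression. Linearizes the coupled
    synaptic dynamics around the stationary bump and projects them onto the
    attractor manifold to obtain closed-form diffusion strengths and drift
    fields induced by frozen heterogeneities (random connectivity, leak
    potential spread, weight jitter); includes a stochastic rate-network
    simulator, a reduced Langevin integrator on the circle, a scaled-down
    conductance-based integrate-and-fire network with spike-based short-term
    plasticity, a firing-rate reduction of the conductance neuron with a
    network tuning procedure, and estimators for diffusion coefficients,
    drift fields, mutual information and distractor sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    boot,
    graphics,
    pracma,
    stats,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
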