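Package: inexsim
Title: Phenomenological Spiking-Network Simulation of Maturing Neuronal
    Cultures on Microelectrode Arrays
Version: 0.1.0
Authors@R:
    person("inexsim", "developers", email = "inexsim@example.org",
           role = c("aut", "cre"))
Description: Simulates spontaneous spiking activity of maturing in vitro
    neuronal networks with the INEX (inhibitory-excitatory) cellular-automaton
    model: an inhomogeneous Poisson spike rule with a one-slice spike-history
    facilitation factor, random excitatory/inhibitory networks with
    triangular-distributed parameters, and a maturation schedule of increasing
    connection probability. Provides the adaptive cumulative-moving-average
    (CMA) interspike-interval burst detector, per-unit spike/burst feature
    extraction, quartile summaries against an embedded microelectrode-array
    reference table, and brute-force grid-search calibration of the model's
    parameter upper bounds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
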