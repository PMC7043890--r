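Package: navlti
Title: Sodium-Channel Long-Term Inactivation as a Molecular Leaky
    Integrator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Continuous-time Markov modelling of voltage-gated sodium (Nav)
    channel gating with a long-term inactivated (LTI) state. Provides a
    Q-matrix engine with matrix-exponential propagation under
    piecewise-constant voltage-clamp protocols, the 13-state LTI and
    12-state non-LTI Nav gating models, macroscopic current simulation,
    pulse-train availability and bi-exponential recovery-from-inactivation
    analysis, discrete-time leaky-integrator models of the LTI-state
    occupancy, seeded synthetic voltage-clamp data generation, and an
    in-silico dynamic-clamp surrogate pacemaker neuron driven by
    model-generated sodium current.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
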