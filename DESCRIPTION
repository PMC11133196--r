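Package: drsirt
Title: Bayesian Item Response Models for Single-Slider and Dual-Range-Slider Responses
Version: 0.1.0
Authors@R: person("drsirt", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A joint Bayesian hierarchical item-response-theory pipeline for
    continuous bounded questionnaire responses collected with visual analog
    scales (single sliders) and dual-range sliders (interval responses).
    Implements the beta response model (BRM) for single sliders and the
    Dirichlet dual-response model (DDRM) for interval responses, a joint
    multitrait-multimethod model with a multivariate-normal person structure
    and identification constraints, Hamiltonian Monte Carlo estimation with
    rank-normalized convergence diagnostics, Pareto-smoothed importance
    sampling leave-one-out cross-validation, a longitudinal measurement
    invariance ladder (configural, metric, scalar, strict), posterior
    reliability and validity summaries, a correlation-based cross-lagged
    panel model, and a synthetic-data generator emulating the two-trait,
    two-format, two-occasion study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
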