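Package: dielstarch
Title: Carbon-Homeostasis Modelling of Diel Starch and Sucrose Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and Bayesian analysis of diel starch-sucrose dynamics in
    plant leaves under the carbon-homeostasis model, in which a clock-gated
    starch degradation rate peaks at dawn and its trough timing defines a
    subjective photoperiod. Provides a fixed-step Runge-Kutta integrator for the
    piecewise light/dark ODE system, the closed-form homeostatic degradation
    profile, a synthetic diel time-series generator emulating long-day and
    short-day harvest designs, adaptive MCMC fitting of the seven model
    parameters with uniform priors and kernel-density MAP estimates, WAIC-based
    selection among sparse mutant-deviation models, quantification of mutant
    effects as log2 fold changes and subjective-photoperiod shifts, and
    estimation of the empirical degradation-rate profile from maltose and
    starch measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    coda,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
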