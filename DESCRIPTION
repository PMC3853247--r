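Package: ifnpkpd
Title: Population PK-PD Modelling of Sustained-Release Interferon-Alpha and
    the Neopterin Response
Version: 0.1.0
Authors@R:
    person("Analysis", "Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structural and statistical machinery for the population
    pharmacokinetic-pharmacodynamic analysis of a sustained-release
    subcutaneous interferon-alpha formulation with neopterin as the
    response biomarker.  Provides the one-compartment PK model with
    parallel zero-order and lagged first-order absorption (solved
    analytically), an indirect-response (turnover) PD model with a single
    transit compartment and a time-increasing EC50, clinical-trial
    simulation with log-normal between-subject variability and
    additive/proportional residual error, approximate marginal-likelihood
    (Laplace/FOCE-I style) estimation with sequential PK to PD coupling,
    non-compartmental analysis, nonparametric bootstrap, and visual
    predictive checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
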