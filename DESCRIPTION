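Package: mothwin
Title: Hierarchical Bayesian Model of Annual Insect Population Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage hierarchical Bayesian model of annual insect
    population dynamics for univoltine species censused as eggs and
    last-instar larvae. Egg-to-larva survival follows a binomial model
    with a complementary log-log link in log egg density and log
    development time, equivalent to survival under a Weibull hazard,
    capturing the "window of vulnerability" to generalist enemies;
    larva-to-next-year-egg productivity follows a Poisson model with
    density dependence on the log scale. Both stages carry normally
    distributed random year effects, with optional weather covariates
    (summer temperature, winter minimum temperature, snow cover, spring
    temperature). Provides MCMC fitting with convergence diagnostics,
    highest-posterior-density summaries, one-step forward prediction,
    posterior predictive checks, multi-year stochastic trajectory
    simulation with extinction tracking, phenology utilities, and a
    synthetic-data generator for simulation studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
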