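Package: hlemc
Title: Healthy Life Expectancy from Interval-Censored Multistate Panel Data
Version: 0.1.0
Authors@R: person("Health-Expectancy", "Modelling Group",
    role = c("aut", "cre"), email = "maintainer@example.org")
Description: Fits a three-state (healthy, disabled, dead) discrete-time Markov
    model with polychotomous logistic transition probabilities in age, sex,
    hypertension and diabetes to interval-censored longitudinal survey panels,
    by maximum likelihood over products of monthly transition matrices
    (interpolated Markov chain). Converts fitted models into multistate life
    tables: state-specific expectancies, total and healthy life expectancy,
    and the percentage of remaining life free of functional incapacity, per
    covariate profile and starting age. Includes a synthetic aging-cohort
    generator emulating a five-wave longitudinal study on aging so the whole
    pipeline is testable without restricted survey microdata, plus a small
    command-line interface for simulate/fit/lifetable runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
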