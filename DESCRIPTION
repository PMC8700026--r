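Package: dmscreen
Title: Cost-Utility Modelling of Type 2 Diabetes Screening Strategies
Version: 0.1.0
Authors@R: person("Model", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A decision-tree plus Markov cohort model for the economic
    evaluation of population-based type 2 diabetes mellitus (T2DM)
    screening delivered at two primary-care tiers (commune health
    stations and district health centers) in a Vietnam-like setting.
    Implements screening cascades chained from test sensitivities and
    specificities, a five-state lifetime cohort model with
    HbA1c-scaled transition and mortality risks, discounted cost, life
    year and QALY accumulation with Simpson's 1/3 within-cycle
    correction, incremental cost-effectiveness and net-monetary-benefit
    ranking with an efficiency frontier, and deterministic (tornado)
    and probabilistic (Monte Carlo, CEAC, cost-effectiveness plane)
    uncertainty analysis. Ships a transcribed parameter table, a
    Gompertz-Makeham life-table generator calibrated to a life
    expectancy target, and synthetic patient-level cost and EQ-5D-5L
    microdata generators with the estimators that summarise them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
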