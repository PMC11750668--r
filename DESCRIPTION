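Package: fuelbudget
Title: Fuel-Budget Accounting for Sub-2-Hour Marathon Metabolism
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic whole-body substrate accounting for running at
    sub-2-hour-marathon intensity. Computes carbohydrate and fat energy
    partitioning from per-minute oxidation rates, muscle-glycogen budgets
    under depletion thresholds, liver-glucose accounting, the exogenous
    carbohydrate oxidation rates required to close the fuel deficit,
    counterfactual scenarios in which fat oxidation is raised, and
    cumulative exogenous-carbohydrate oxidation kinetics (amounts oxidized
    versus ingested from sports drinks). Ships printed male and female
    athlete fuel profiles as fixtures, a synthetic-curve generator for
    saturating oxidation-rate ramps, and a command-line report tool.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    withr,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
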