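Package: cariescea
Title: Cost-Effectiveness of School-Based Caries Prevention via System Dynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time stock-and-flow (system dynamics) simulation of
    dental caries progression in a closed school-age cohort, with provider
    perspective costing and cost-effectiveness analysis of supervised
    toothbrushing and dental sealant programmes. Provides the compartmental
    simulator, coverage-adjusted intervention scenarios, CPI-standardised unit
    costing, cost-effectiveness and incremental cost-effectiveness ratios with
    dominance classification, deterministic multi-way sensitivity grids, and
    least-squares calibration of flow fractions and initial stocks to
    aggregate cohort trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
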