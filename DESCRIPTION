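Package: telecea
Title: Cost-Effectiveness of Telemonitoring for Heart Failure Under
    Pandemic Care Avoidance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Markov cohort decision model comparing usual multidisciplinary
    heart-failure care under COVID-19-related care avoidance with the same
    care plus smartphone telemonitoring. Patients move monthly among NYHA
    functional classes I-IV and death, with heart-failure hospitalization
    and all-cause mortality as monthly events modified by care-avoidance
    and telemonitoring risk ratios. The package computes discounted costs
    and quality-adjusted life-years per strategy, incremental
    cost-effectiveness ratios and net monetary benefit, one-way and two-way
    deterministic sensitivity analyses with threshold search, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves, and
    an individual-level microsimulation that serves as a brute-force check
    of the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
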