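Package: longsig
Title: Longitudinal Pharmacovigilance Signal Detection and Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Optimise", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for drug-safety surveillance in longitudinal cohort data,
    built around the patient-month as the unit of observation. Implements
    disproportionality measures (reporting odds ratio, proportional and
    relative reporting ratios, incidence rate ratio) with crude, subgrouped
    and inverse-probability-of-treatment weighted pathways; Bayesian
    shrinkage of the information component with posterior false discovery
    rates; a protopathic-bias filter comparing treatment initiations before
    and after incident events; a tiered signal generation procedure;
    marginal structural cohort analyses of time-varying treatment effects;
    and a synthetic multiple-sclerosis cohort simulator with known ground
    truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
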