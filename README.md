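# longsig

Longitudinal pharmacovigilance signal detection and weighted cohort
analysis for chronically treated populations, built for the
disease-modifying-therapy (DMT) safety setting in multiple sclerosis.

## Who this is for

Biostatisticians and pharmacoepidemiologists analysing longitudinal
cohort data — participant demographics, treatment episodes, adverse
events, labs and disability scores — who need drug-safety signal
detection that accounts for the two biases that dominate this setting:
confounding by indication (including its time-varying form) and
protopathic bias.

## What it computes

The unit of observation is the **patient-month**: one 30-day bin of one
participant's follow-up, classified by drug exposure (three exposure
definitions: current-or-previous month, preceding six months, ever) and
incident-event occurrence. On the resulting 2×2 patient-month tables:

* **Disproportionality measures** — reporting odds ratio
  `ROR = n11·n00/(n01·n10)`, proportional reporting ratio
  `PRR = (n11/n1.)/(n01/n0.)`, relative reporting ratio
  `RRR = n11·n../(n.1·n1.)`, with Woolf log-scale confidence intervals.
  In the longitudinal formulation the PRR *is* the incidence rate ratio;
  the package verifies this identity to 1e-10 against a log-linear model
  fit.
* **BCPNN shrinkage** — conjugate Bayesian posterior of the information
  component `IC = log2(RRR)` with independence-favoring priors, per-signal
  posterior null probability `Pr(IC ≤ 0)` (the FDR statistic) by seeded
  Monte Carlo.
* **LEOPARD** — a protopathic-bias filter: an exact one-sided binomial
  test at the 50% significance level comparing first-initiations of the
  drug in the month after versus the month before the incident event.
* **The tiered signal procedure** — Level 1 (minimum report: 3
  participants for second-generation drugs, 5 for first-generation, 2
  pediatric), Level 2 (lower 95% bound of the ROR/IRR > 1), Level 3
  (FDR < 5% and not discarded by LEOPARD), run over crude, subgrouped and
  IPTW-weighted pathways, with pooled ranked signal lists and a
  drug–drug–event interaction scan.
* **Cohort analyses** — a new-user primary analysis (episode-level
  propensity weights, stratified weighted Cox regression) and secondary
  marginal-structural analyses with stabilized inverse-probability-of-
  treatment weights updated at 6-month intervals and four exposure models
  (current class, carryover, cumulative, time-decayed cumulative), plus a
  switch-interaction tertiary analysis.
* **A synthetic cohort generator** with known ground truth (planted rate
  ratios, tunable time-varying confounding, a protopathic scenario) used
  by the validation suite for parameter recovery.

## Worked example

Simulate a 2000-patient, 60-month cohort with a planted rate ratio of 3
for natalizumab–infection, then run the crude and weighted signal
pathways:

```r
library(longsig)

cfg <- scenario_presets("planted_signal", n_patients = 2000,
                        horizon_months = 60, seed = 42)
sim <- simulate_cohort(cfg)
res <- run_pathways(sim, exposure_def = "E1",
                    pathways = c("crude", "weighted"), seed = 42)
res$pooled_level3
#>             drug  drug2                        event n_pathways best_fdr
#> 1:   NATALIZUMAB   <NA>                    INFECTION          2  0.00000
#> 2: TERIFLUNOMIDE   <NA>                    OTHER_SAE          2  0.00825
#> 3:   NATALIZUMAB   <NA> MALIGNANCY_TREATMENT_RELATED          2  0.04089
```

The planted signal tops the pooled Level-3 list (flagged by both
pathways, posterior null probability ~0); the other rows are the
small-count false positives such a screen is expected to admit at the 5%
FDR gate. Drilling into the planted pair:

```r
res$signals[drug == "NATALIZUMAB" & event == "INFECTION",
            .(pathway, n11, ror, lower95, ic_mean, p_null, level3)]
#>     pathway n11  ror lower95 ic_mean p_null level3
#> 1:    CRUDE  41 3.65    2.64    1.68      0   TRUE
#> 2: WEIGHTED  41 3.64    2.65    1.67      0   TRUE
```

41 exposed patient-months with an incident infection give a crude ROR of
3.65 (lower 95% bound 2.64, well above the Level-2 threshold of 1) and a
shrunk information component of 1.68 bits ≈ log2(3.2) — close to the
planted log2(3) = 1.58. The individual measures print with their
intervals:

```r
tab <- contingency_table(41, 2192, 450, 87852)
ror(tab)
#> ROR = 3.652 [2.645, 5.041] (95% CI, log-SE 0.165)
prr(tab)
#> PRR = 3.603 [2.624, 4.947] (95% CI, log-SE 0.162)
```

The confounding-recovery experiment (see the methods vignette,
`vignettes/longsig-methods.Rmd`) is run by the acceptance suite: on the
`confounded` preset with a true class-level rate ratio of 2, the crude
pathway is biased upward by ~40% while the IPTW-weighted estimate
recovers 2 within a few percent with weighted covariate standardized mean
differences below 0.1.

## Command line

```sh
Rscript inst/cli/longsig.R simulate --preset planted_signal --n 2000 \
        --months 60 --seed 42 --out cohort_dir
Rscript inst/cli/longsig.R signals --cohort cohort_dir --exposure-def E1 \
        --pathways crude,weighted --seed 42 --out signals_dir
Rscript inst/cli/longsig.R interim --cohort cohort_dir --out interim_dir
Rscript inst/cli/longsig.R cohort  --cohort cohort_dir --outcome INFECTION \
        --out cohort_out
```

(After installation the script lives at
`system.file("cli", "longsig.R", package = "longsig")`.)

## Input file layout

`read_cohort()`/`write_cohort()` use a directory of UTF-8 CSVs with
ISO-8601 dates (schema `longsig-cohort v1`): `participants.csv` (id, sex,
birth_date, enrolment_date, optional exit_date and baseline covariates),
`exposures.csv` (participant_id, drug, class, start_date, end_date),
`events.csv` (participant_id, category, subtype, event_date), `labs.csv`
(participant_id, date, analyte, value, lln, uln) and optionally
`edss.csv` (participant_id, date, edss).
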