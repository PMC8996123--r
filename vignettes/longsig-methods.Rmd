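---
title: "Methods: longitudinal signal detection and weighted cohort analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal signal detection and weighted cohort analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longsig)
```

## The problem

Observational cohorts of people with multiple sclerosis on disease-modifying
therapies (DMTs) can reveal serious adverse events (SAEs) that trials are too
small or too short to see, but two biases stand between the raw data and a
credible safety signal:

* **confounding by indication**, including its time-varying form: sicker
  patients are preferentially switched onto newer (second-generation) DMTs,
  and the same disease activity that drives the switch also raises event
  rates; past treatment influences future covariates which influence future
  treatment;
* **protopathic bias**: a treatment started *because of* the prodrome of an
  event is then blamed for the event.

`longsig` implements a complete analysis chain for this setting, with the
**patient-month** — one 30-day bin of one participant's follow-up — as the
unit of observation, plus a synthetic-cohort generator whose ground truth is
known, so that every estimator in the package can be validated by parameter
recovery rather than by fiat.

## The patient-month panel

Months are fixed 30-day bins counted from each participant's own enrolment
date. Calendar months are deliberately not used: participants enrol on
arbitrary dates, calendar months vary in length, and the study design has no
common calendar milestone; fixed bins remove month-length artifacts. The
anchor date of each bin is retained for reporting.

Date intervals are half-open `[start, end)`. An exposure episode touching
*any* day of a bin marks that bin's current-month exposure — the coarseness
this introduces is intrinsic to patient-month analyses and is exactly the
channel through which protopathic bias enters (see LEOPARD below).

Three exposure definitions map episodes to patient-month flags:

| code | window |
|------|--------|
| `E1` | the month of interest or the previous month |
| `E2` | the month of interest or the preceding 6 months |
| `E3` | any prior time in the treatment history (including pre-enrolment) |

`E2` includes the current month so that the definitions nest
(`E1` ⇒ `E2` ⇒ `E3`), a property the test suite checks against a brute-force
day-by-day oracle. Only **incident** events are analyzed — the first
occurrence per participant — and follow-up is censored at that occurrence.

Clinical outcome derivation follows the standard conventions: lymphopenia
grades at the 800/500/200 cells/mm³ boundaries (the printed grade
definitions overlap at the boundaries; we resolve them as lower-inclusive
half-open bins, so a boundary value takes the less severe grade), liver
injury as ALT/AST strictly above 2.5× (moderate) or 5× (severe) the upper
limit of normal, and disability progression as an EDSS measurement at least
1.0 point above the immediately preceding measurement.

## Disproportionality measures

For a drug–event pair the at-risk patient-months form a 2×2 table
(`n11` exposed/event, `n10`, `n01`, `n00`), and

$$\mathrm{ROR}=\frac{n_{11}n_{00}}{n_{01}n_{10}},\qquad
\mathrm{PRR}=\frac{n_{11}/n_{1\cdot}}{n_{01}/n_{0\cdot}},\qquad
\mathrm{RRR}=\frac{n_{11}\,n_{\cdot\cdot}}{n_{\cdot1}\,n_{1\cdot}}.$$

In this longitudinal formulation the PRR *is* the incidence rate ratio
(events per patient-month exposed over unexposed); `irr_from_panel()`
computes it both as a rate quotient and as the exposure coefficient of a
log-linear Poisson model, and the identity holds to 1e-10 relative
tolerance in the test suite, weighted or not.

Two numerical choices are ours — no interval method is canonical for
longitudinal disproportionality:

* confidence intervals are Woolf/delta-method intervals on the log scale
  (e.g. `SE = sqrt(1/n00 + 1/n01 + 1/n10 + 1/n11)` for the ROR);
* a zero cell yields a **flagged undefined** estimate rather than a
  continuity correction. The Level-1 minimum-report gate guarantees
  `n11 ≥ 2` for every screened pair, and Haldane-style corrections would
  distort weighted (real-valued) cells.

With inverse-probability weights, each cell is the sum of the weights of its
patient-months; weighted cells are not multinomial counts, so the weighted
pathway's Level-2 interval comes from the robust (participant-clustered
sandwich) variance of the weighted Poisson rate model instead of the Woolf
formula.

## BCPNN shrinkage

Sparse tables make the crude measures volatile. The shrinkage model is the
classical conjugate construction: the information component
`IC = log2 P(drug, event) / (P(drug) P(event))` (the base-2 logarithm of
the RRR) receives a Dirichlet prior over the 2×2 cell probabilities whose
components are proportional to the product of the posterior-mean marginals
(themselves under Beta(1,1) priors), scaled so the joint prior count is
`gamma11 = 1`. With these hyperparameters the prior expectation of the IC
is zero — the prior "believes" in independence and pulls small-count
estimates toward the null.

`ic_posterior()` reports the standard moment approximation (`ic_mean`,
`ic_sd`) and, from seeded Monte-Carlo draws of the Dirichlet posterior, the
95% credible bounds and `p_null = Pr(IC ≤ 0 | data)`. The Monte-Carlo
sample is authoritative for the tail quantities; the moment approximation
is what `ic_mean` reports, which matters for one subtle reason: for the
symmetric table (1,1,1,1) the moment approximation is exactly 0 while the
posterior *mean of the logarithm* is about −0.11 bits (Jensen's
inequality). Asymptotically both converge to `log2(RRR)`.

`p_null` is each signal's FDR statistic ("the probability of no
association"); `fdr_for_list()` also reports the ranked list's running FDR
(cumulative mean of `p_null` sorted ascending). The Level-3 gate consumes
the per-signal value — either could reasonably gate a screen, and the
per-signal gate is the stricter, more conservative choice for an
individual signal; both are reported.

## LEOPARD

The protopathic-bias filter compares, per signal, how many participants'
*first* initiation of the drug falls in the month after the incident event
versus the month before. Under the null of no protopathic pattern the split
is symmetric, so `p = Pr(X ≥ n_after)` for `X ~ Binomial(n_before +
n_after, ½)`; the test is run at the 50% significance level and the signal
is discarded when `p < 0.5`.

Design choices fixed here: the comparison window is
one 30-day month on each side (configurable, but the same width on both
sides — otherwise the ½ null is wrong); only the first initiation per
participant counts, matching incident-event logic; and a same-day tie
counts as "after", the conservative direction (it favors discarding
protopathic-like signals).

## IPTW and the marginal structural model

Treatment assignment is modeled at 6-month intervals (six 30-day bins) as a
three-class multinomial logit — no treatment, first-generation DMT,
second-generation DMT — on the previous interval's class plus covariates.
The fitter is an in-package Newton–Raphson routine (the environment's
recommended-package multinomial fitters are not available, and the model is
small). Stabilized weights follow the standard construction

$$w_i(t)=\prod_{k\le t}
\frac{\Pr(A_k=a_{ik}\mid A_{k-1},\text{baseline})}
     {\Pr(A_k=a_{ik}\mid A_{k-1},L_k)},$$

with the denominator's covariate history entering as the current-interval
values plus previous class (first-order Markov, to bound model dimension;
configurable). Weights are truncated at the 1st/99th percentiles by default
(extreme weights are the known failure mode of MSM estimation); truncation
is logged and can be disabled. A positivity violation (denominator
probability at machine zero) is an error naming the offending stratum, not
a silent clamp.

Balance diagnostics (`balance_table()`) default to the standard
per-timepoint check: each interval row weighted by the inverse full
propensity of its observed class, maximum pairwise standardized mean
difference across the three classes. The *cumulative* stabilized weights do
not make pooled cross-sectional SMDs vanish even when the model is correct
— they balance covariates conditionally on treatment history — so the
cumulative mode is reported separately.

The primary cohort analysis is simpler by design: new users (no
second-generation DMT before enrolment) contribute an unexposed episode
from enrolment to first second-generation initiation and an exposed episode
until cessation, stratified by prior first-generation use, with
episode-level inverse-propensity weights from a pooled logistic model of
exposure on covariates at episode start. Secondary analyses use four
exposure models on the interval panel: current class (A), current class
plus a carryover indicator for any *other* class in the past 6 months (B),
cumulative months per class through the end of the current interval (C),
and time-decayed cumulative exposure with each past month contributing
`2^(-lag/half-life)`, half-life 6 months (D). Model C counts through the
interval's end (an 18-month continuous exposure shows 18 at its third
interval); model D decays strictly historical months relative to the
interval start. The tertiary analysis adds current-class × carryover
interactions to model B.

Outcome models are fit either by weighted time-varying Cox regression
(months since enrolment as the time scale — enrolment is the only common
origin in a study with no unifying clinical milestone — Efron ties, robust
participant-clustered variance) or by the pooled discrete-time log-linear
equivalent. The two agree to within a few percent once event counts are in
the hundreds; at a few dozen events their Monte-Carlo difference exceeds
the asymptotic agreement, which is why the agreement test runs at ~700
events.

## The signal generation procedure

For each exposure definition and pathway:

1. **Level 1** — minimum-report gate: an event must occur, in an exposed
   patient-month, in at least 3 distinct participants for second-generation
   drugs, 5 for first-generation (whose safety profile is established), 2
   in the pediatric analysis. "Affected participant" is interpreted as a
   distinct participant whose incident event month is exposed under the
   active definition (the natural reading of "reported in k participants"
   for an exposure-linked screen; logged as a design choice).
2. **Level 2** — the lower 95% bound of the ROR (equivalently the IRR)
   strictly exceeds 1. Subgrouped pathway: in at least one subgroup;
   weighted pathway: robust interval of the weighted IRR.
3. **Level 3** — BCPNN `p_null` strictly below 5% *and* not discarded by
   LEOPARD (an untestable LEOPARD retains the signal, flagged). Shrinkage
   and LEOPARD are evaluated for Level-2 signals only, mirroring the staged
   procedure.

The three pathways are crude, subgrouped (default subgroups sex × age band
<40/≥40 × prior first-generation use, merged below 200 patient-months), and
IPTW-weighted. Pooled Level-2/Level-3 lists rank by the number of pathways
flagging the signal, then by the best statistic (largest lower bound /
smallest FDR), with lexicographic tie-breaks for determinism. The
drug–drug–event scan defines pair exposure as patient-months qualifying for
both drugs under the active definition (there is no canonical background
definition for treatment-interaction scans; this one is documented here)
and reuses the same machinery
with the stricter of the two drugs' thresholds. The interim analysis runs
the crude pathway only, plus constant-hazard unadjusted Poisson regressions
of first-any-SAE on current treatment class. The pediatric analysis
restricts to patient-months at age < 18, crude pathway, threshold 2.

## The synthetic cohort: what it emulates, and what a green test shows

`simulate_cohort()` generates the stated world the validation runs in:

* monthly follow-up over a configurable horizon (default 60 months,
  n = 2000–4000), ~72% female, enrolment ages ~N(40, 11) truncated to
  12–70 (a small pediatric fraction), withdrawal ~0.4%/month;
* latent disease activity `z` (monthly AR(1), ρ = 0.85) drives relapses
  (baseline 0.03/month, treatment reduces them: RR 0.7 on
  first-generation, 0.45 on second-generation) and stepwise EDSS
  worsening, reviewed and *measured* at 6-month decision points;
* treatment class re-assessed at decision points by a multinomial logit on
  the previous class (persistence bonus 2.5, untreated inertia 1.0,
  intercepts −1.2 / −0.7) and the **observed** covariates (measured EDSS,
  relapses in the preceding 6 months) scaled by the confounding strength
  `gamma`. Because assignment and outcome hazards depend only on observed
  covariates, the IPTW denominator model is correctly specified and
  parameter recovery is a fair test of the estimator, not of model
  misspecification;
* SAE hazards per category (infections 0.005/month, other SAE 0.004,
  COVID-19 0.002, opportunistic infections 8e-4, treatment-related
  malignancy 5e-4, death 4e-4) multiplied by the planted rate-ratio map,
  the covariate multiplier `exp(gamma_out(0.25(EDSS−2) +
  0.4·relapses_6m))`, and optional carryover and protopathic factors;
* episodes start with a uniform within-bin day offset; cessation falls on
  the bin boundary so the analyst's month grid reproduces the generative
  treatment state.

Presets freeze the validation scenarios: `null` (all RR 1, `gamma` 0),
`planted_signal` (RR 3 for natalizumab–infection), `confounded`
(`gamma = gamma_out = 1.3`, class-level RR 2 for infection — the
coefficients were calibrated once to produce the stated crude-versus-
weighted bias separation and then frozen), `protopathic` (hazard ×3 in the
month before each initiation, infection baseline 0.01, 3-month decision
cadence with low persistence so initiations are frequent), and
`switching_carryover` (RR 2 for 6 months after leaving first-generation
DMT, expressed only while on second-generation DMT).

What the generator does **not** emulate: real MS natural history
calibration, pregnancy, site effects, informative visit schedules,
differential event ascertainment by treatment, MedDRA coding, and
unmeasured confounding. A green recovery test therefore establishes that
the estimators do what they claim *when their assumptions hold*, not that
those assumptions hold in any particular real cohort.

### The protopathic mechanism at month resolution

The generator raises the hazard in the `lead` months *preceding* each
initiation. At 30-day-bin resolution such an event lands in an exposed
patient-month only when the event and the initiation share a bin (the
initiation day is uniform within its bin), which is precisely how
protopathic bias contaminates patient-month disproportionality — and why
spurious Level-2 signals are rare at multiplier 3 while the LEOPARD
before/after contrast is strongly informative. The power check therefore
applies LEOPARD to the planted drug–event pairs with a testable count
(≥ 5 initiations near events) rather than conditioning on a Level-2 flag,
which would leave an almost empty denominator.

### Null calibration of the Level-2 rule

The "lower 95% bound > 1" rule has one-sided error 2.5% only
asymptotically. At desk-scale counts the exact error of the Woolf rule is
3.0–3.6% (skewness of log counts), and conditioning on the Level-1 gate
raises the conditional rate among screened pairs to roughly 5%. The
calibration test therefore compares the empirical per-pair flag rate with
the rule's exact null rejection rate computed by a matched-margin
Monte-Carlo oracle — the same construction used for LEOPARD's exact null
rejection mass — rather than with the asymptotic 2.5%.

## Numerical and engineering choices

* Determinism: every stochastic component is seeded; the pipeline derives a
  stable per-record seed for the BCPNN Monte Carlo, so identical inputs and
  seed give byte-identical signal tables. Derived seeds stay below 2^31.
* Monte-Carlo budget: `ic_posterior()` defaults to 1e5 draws; replicate
  simulation tests use 2e4 draws to stay inside the runtime budget (the
  `p_null` Monte-Carlo error is then ~0.003, far below the 5% gate's
  resolution).
* Degenerate inputs: zero-cell tables are flagged, never corrected;
  both-zero LEOPARD counts are "untestable, retained"; a treatment class
  never observed in the assignment model is an error; inestimable model
  terms are reported as `NA` with a warning, not dropped silently.
* Episode conflicts: same-drug overlaps merge; different-drug overlaps are
  truncated at the later episode's start (switch semantics) with a warning;
  anything still overlapping after normalization is rejected.
* Missing covariates: last observation carried forward within participant;
  participants with no usable covariates are excluded from the weighted
  pathway only, with a logged warning.

## Known limitations

* The weighted-cell BCPNN treats weighted patient-month sums as effective
  counts; this is a documented approximation without an exact posterior
  justification.
* The subgrouped pathway's "signal in at least one subgroup" rule is
  deliberately sensitivity-oriented and inflates the family-wise Level-2
  rate (~8 subgroups × per-subgroup error); the Level-3 shrinkage stage is
  what reins this in.
* Episode-level propensity weights control only covariates measured at
  episode start; time-varying confounding within long episodes is out of
  that design's reach (that is what the MSM pathway is for).
* The drug–drug–event scan's background definition (all months not
  co-exposed) is one of several defensible choices and should be revisited
  for any specific interaction hypothesis.
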