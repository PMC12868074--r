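---
title: "Model structure, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalcea)
```

This vignette documents the science inside `renalcea`: the cohort model
and its conventions, the parameters and where their defaults come from,
the weighting pipeline, what the synthetic-cohort generator does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## The cohort model

A cohort of patients treated for T1 renal cell carcinoma — by
percutaneous cryoablation (PCA) or robot-assisted partial nephrectomy
(RAPN) — is advanced through four states in monthly cycles:
*stable disease*, *local recurrence*, *metastatic disease* and *death*
(absorbing).  Monthly transition probabilities are taken literally as
per-cycle probabilities (no rate conversion): local recurrence 0.0018,
metastatic progression 0.0035 (from stable disease and from local
recurrence alike) and background mortality 0.0012.  In the metastatic
state, background and disease-specific mortality act as independent
competing risks, `1 − (1 − p_bg)(1 − p_ms)`, which avoids double
counting and is symmetric in the two hazards.

**Cycle-0 convention.** Cycle 0 is the procedure month.  The cohort
occupies stable disease but accrues a fixed intervention-month QALY of
0.058 (equivalent to spending the month in the local-recurrence state,
0.70/12) instead of `u_stable/12`, minus the expected complication
disutility `p_complication × 0.05`.  Costs at cycle 0 are the procedure
cost, the expected complication cost `p_complication × €4,332` and the
bed-night cost `c_bed_night × mean_los`, all undiscounted.  Transitions
begin at the cycle-0→1 step; cycles 1 … 59 accrue annual state utilities
divided by 12 and the monthly metastatic-state cost of €2,500, each
multiplied by the discount factor `(1.03)^(−m/12)`.  A 5-year horizon
(60 cycles) keeps the model inside the evidence window without
extrapolation.

**Half-cycle correction** is available as a flag
(`shared_params(half_cycle_correction = TRUE)`, mid-cycle averaged
occupancies) but off by default: with monthly cycles the correction is
an order of magnitude below the decision-relevant differences, and the
uncorrected accrual keeps the closed-form identities used in testing
exact.

**State cost assignment.** The €2,500/month "advanced disease" cost is
assigned to the metastatic state only; the local-recurrence state
carries no monthly cost by default.  Both are configurable
(`c_advanced_monthly`, `c_local_recurrence_monthly`) because the
assignment of downstream-treatment costs between recurrence and
metastasis is a genuinely open choice.

## Metastatic mortality and calibration

Survival after metastatic progression follows a parameterised curve.
The default is an **exponential** (constant monthly death probability) —
the minimal memoryless choice that needs no tunnel states — anchored on
roughly 10% 5-year overall survival under targeted systemic therapy in
metastatic renal cell carcinoma: `p_month = 1 − 0.10^(1/60) ≈ 0.0376`.
A Weibull family is provided through a time-in-model approximation
(`p(t) = 1 − S(t+1)/S(t)`) for shape-sensitive analyses, but is off by
default because its extra parameter is not identifiable from the
available anchors.

Because that anchor is soft, `calibrate_metastatic_mortality()` can
re-fit the monthly probability to either (a) a stated metastatic
survival fraction at a stated month, or (b) a target discounted QALY or
cost total for a named strategy, by monotone bisection on `[0, 1]`
(relative tolerance 1e-6, at most 200 iterations, with an explicit
infeasibility error when the anchor is not bracketed).  Calibrating to a
5-year RAPN QALY total of 3.315 yields `p_month ≈ 0.0090` and a
discounted RAPN cost of ≈ €28,493.

## The bed-night tariff

The per-night hospital cost deserves its own note because it is
*derived*, not quoted.  With procedure costs €7,427 (PCA) and €15,293
(RAPN), complication probabilities 5.5%/2.5% and a €4,332 complication
cost, the structural incremental cost is

```
(7427 + 0.055·4332) − (15293 + 0.025·4332) = −7736.04 €.
```

A base-case incremental cost of −€8,725 therefore leaves a residual of
−€988.96.  Spread over the length-of-stay difference (1.13 vs 1.90
nights) this residual is exactly a per-night tariff of
`988.96 / 0.77 = €1,284.4`, and under that tariff both arms imply an
identical metastatic-state cost (≈ €9,679) — the only reading under
which the two arms' cost totals are mutually consistent given shared
transition probabilities.  The packaged base case
(`basecase_table1.yaml`) therefore sets `c_bed_night = 1284.4`; the
constructor default remains 0 so that analyses without bed-day costing
are one flag away.

## Two published claims the model cannot reproduce from printed inputs

The package computes, rather than asserts, its base case — and two
headline features of the published analysis turn out not to follow from
the printed inputs alone.  They are left visible (two acceptance tests
fail by design) rather than patched:

* **The sign of the QALY difference.** With identical transition
  probabilities in both arms, the only QALY difference is the expected
  complication disutility, `ΔQALY = −(0.055 − 0.025) × 0.05 = −0.0015`,
  slightly *against* PCA.  A reported +0.008 QALY advantage for PCA
  would require arm-specific intervention-month utilities that are not
  printed.  Consequently the model classifies the base case as
  cost-saving with a near-zero QALY loss (ICER ≈ €5.8M saved per QALY
  forgone, far above any threshold; NMB strongly positive) rather than
  strictly dominant.
* **The tornado's leading parameter.** The RAPN procedure-cost swing is
  exactly `2 × 0.2 × 15293 = €6,117` (it enters the incremental cost
  linearly and undiscounted), while the per-arm metastasis-probability
  swing is ≈ €5,000–5,250 for *any* exponential metastatic mortality in
  the plausible range — the metastatic-state cost (≈ €9.7k per entrant)
  plus the €40,000/QALY-valued survival channel cannot reach €15.3k of
  NMB leverage under the stated inputs.  So metastasis risk ranks
  second and third, not first.

Neither discrepancy changes the decision: every parameter's ±20% sweep
leaves the NMB positive (minimum ≈ €5,600).

## Deterministic sensitivity analysis

`tornado()` sweeps 17 scalar inputs at ±20% of their base values:
background mortality, metastatic mortality, the three state utilities,
the intervention-month QALY, the complication disutility, the
complication and advanced-disease costs, and — per arm — procedure cost,
complication probability, local-recurrence and metastasis probability.
The per-arm event probabilities share a base value but are varied one
arm at a time, which is how a treatment-specific shift in oncological
risk propagates to the NMB.  Willingness to pay, the discount rate and
the horizon define the decision context and are excluded from the sweep
(the discount rate and bed-night tariff remain addressable through
`one_way()`).  Probabilities and utilities are clamped to `[0, 1]` with
a warning when ±20% would leave the domain; entries are ordered by
`|NMB_high − NMB_low|` with lexicographic tie-breaks, and each run
restores the base model exactly.

## The weighting pipeline

Treatment assignment in the observed cohort is confounded by
indication, so time-to-event comparisons use stabilized
inverse-probability-of-treatment weighting:

* **Propensity model:** logistic regression (IRLS maximum likelihood)
  of treatment on the six named confounders — age, sex, tumor size,
  RENAL score, ECOG performance status and age-adjusted CCI.  The
  ordinal scores enter as integers, which is parsimonious at these
  sample sizes; missing-covariate rows are dropped complete-case with a
  logged count; separation is detected and reported as an error naming
  the covariate rather than returned as a divergent fit.
* **Weights:** `P(treated)/e` and `(1 − P(treated))/(1 − e)` with the
  marginal estimated from the sample; stabilized weights keep the
  pseudo-population near the arm sizes.  Scores numerically at 0/1 are
  an error; optional symmetric trimming (e.g. at 0.01/0.99) is logged,
  never silent.
* **Balance:** weighted means/SDs with Welch-type tests on effective
  sample sizes for continuous covariates; weighted proportions,
  chi-square-type tests and the multi-level Mahalanobis-form
  standardized difference for categorical ones.  The conventional
  SMD < 0.1 threshold is the balance target.
* **Hazard ratios:** weighted Cox partial likelihood with Breslow tie
  handling (the simplest consistent choice, and the one with a tractable
  independent oracle) and a mandatory robust sandwich variance — the
  naive information is invalid under weighting.  Weighted Kaplan–Meier
  curves use the weighted product-limit factors.
* **Proportions:** complication rates compare via the pooled
  two-proportion z-test (equivalent to the uncorrected chi-square).

## The synthetic-cohort generator

`synthetic_scenario()` encodes a generative emulation of the study
population: marginal covariate distributions (pooled means/SDs and
category frequencies), a logistic propensity model whose coefficients
make cryoablation patients on average ≈5 years older, ≈6 mm smaller in
tumor size, ≈0.8 points higher in CCI, ≈4.5 mL/min lower in eGFR and
≈0.2 points worse in ECOG, exponential event times with log-linear
covariate effects (tumor size and RENAL score drive recurrence and
metastasis; age and CCI drive background death; the true treatment
effect defaults to null), per-arm complication Bernoullis, a
day-case/inpatient length-of-stay mixture (day-case probability 85/91,
counted as 1 day, inpatient mean 3.0 nights, so the PCA mean is
103/91 ≈ 1.13), and uniform administrative censoring on 18–42 months,
which puts median follow-up near 30 months.  Comorbidity is linked to
age through a monotone deterministic base plus Poisson noise — the real
joint dependence among CCI, ASA, ECOG and age is unknown, and this
independence-plus-one-link structure is a documented assumption, not an
estimate.

What passing tests on this generator show is that the pipeline recovers
known truth under the *assumed* structure: proportional hazards,
exponential baselines, correctly specified propensity covariates, no
unmeasured confounding.  Real registry data violate several of these
(non-proportional hazards after ablation, measurement error in eGFR,
informative censoring), so the simulation results certify the
machinery, not the clinical conclusions.

## Numerical choices and problem sizes

All arithmetic is double precision; totals are rounded only at
presentation (cents, 3-decimal QALYs).  Bisection tolerances are
relative 1e-6; trace conservation is asserted to 1e-9 and the
matrix-power oracle to 1e-10.  The test suite uses cohorts of 120–20,000
with fixed seeds, 1,000 random parameter draws for conservation
properties, and a 500-replicate × n = 500 coverage study for the null
treatment effect (IPTW CI coverage ≈ 95–96% vs crude ≈ 83% under
confounding); these sizes make the Monte-Carlo error small relative to
every asserted margin while keeping a full run in tens of seconds.

## Known limitations

Patient-level microsimulation, probabilistic sensitivity analysis,
multi-way comparisons, matching-based adjustment, multiple imputation
and competing-risks regression are out of scope.  The model has no
T1a/T1b subgrouping, and the exponential metastatic-mortality default
is an anchor-based stand-in for an unpublished survival curve — any
serious reuse should re-anchor it with `calibrate_metastatic_mortality()`
against setting-specific survival data.
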