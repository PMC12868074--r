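# renalcea

Cost-effectiveness analysis of percutaneous cryoablation (PCA) versus
robot-assisted partial nephrectomy (RAPN) for stage T1 renal cell
carcinoma, for health-economic and clinical-epidemiology analysts.

The package implements two connected pieces:

1. **A Markov cohort cost-utility model.** A treated cohort moves through
   four health states — stable disease, local recurrence, metastatic
   disease, death — in monthly cycles over a 5-year horizon.  From stable
   disease the monthly transition probabilities are `p_lr = 0.0018`,
   `p_met = 0.0035` and background mortality `p_bg = 0.0012`; metastatic
   patients face background and disease-specific mortality as independent
   competing risks, `p_death = 1 − (1 − p_bg)(1 − p_ms)`.  Each cycle `m`
   accrues state utility `u_s/12` and state costs, discounted by
   `(1 + r)^(−m/12)` at `r = 3%`/year; cycle 0 is the procedure month
   (procedure cost, expected complication cost and disutility, fixed
   intervention-month QALY 0.058).  Arms are compared by incremental cost
   and QALYs, the ICER/dominance classification and the net monetary
   benefit `NMB = λ·ΔQALY − ΔCost` at `λ = €40,000`/QALY, with a ±20%
   one-way deterministic sensitivity analysis (tornado) over all 17
   scalar inputs.

2. **The observational pipeline that feeds it.** A propensity model
   (logistic regression of treatment on age, sex, tumor size, RENAL
   score, ECOG and age-adjusted CCI), stabilized
   inverse-probability-of-treatment weights, covariate balance
   diagnostics (weighted SMDs and tests), weighted Cox hazard ratios
   with robust sandwich variance, weighted Kaplan–Meier curves, and a
   pooled two-proportion z-test for complication rates.  Because no
   patient-level data are shipped, a seeded synthetic-cohort generator
   emulates the confounding-by-indication structure (PCA patients older,
   smaller tumors, more comorbidity, poorer renal function and
   performance status).

## Worked example

```r
library(renalcea)

prm <- load_parameters(system.file("extdata", "basecase_table1.yaml",
                                   package = "renalcea"))

# calibrate exponential metastatic mortality to a 5-year QALY anchor
spec <- calibrate_metastatic_mortality(prm$shared,
  list(type = "outcome", strategy = prm$strategies$RAPN,
       component = "qaly_discounted", target = 3.315))
prm$shared$met_mortality <- spec

rapn <- run_strategy(prm$strategies$RAPN, prm$shared)
pca  <- run_strategy(prm$strategies$PCA,  prm$shared)
incremental_analysis(rapn, pca)
#> Incremental analysis: PCA vs RAPN (WTP 40,000 EUR/QALY)
#>   arm     cost qalys delta_cost delta_qalys    icer     nmb
#>  RAPN 28493.10 3.315         NA          NA    <NA>      NA
#>   PCA 19768.07 3.313   -8725.03      -0.002 5816685 8665.03
```

PCA saves €8,725 over five years at near-identical effectiveness
(3.313 vs 3.315 discounted QALYs; the −0.002 QALY difference is the
expected disutility of its higher complication rate), giving a positive
net monetary benefit of €8,665 at €40,000/QALY — PCA is cost-effective.
The tornado confirms robustness: every low/high NMB in the ±20% sweep
stays positive (minimum ≈ €5,600), led by the RAPN procedure cost and
the per-arm metastasis probabilities.

The full pipeline — synthetic cohort, IPTW balance, weighted hazard
ratios, CEA and tornado, written as a CSV/JSON report bundle:

```r
report <- run_pipeline(prm, scenario = synthetic_scenario(), seed = 1,
                       out_dir = "run1")
print(report)
```

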