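Package: renalcea
Title: Cost-Effectiveness of Percutaneous Cryoablation Versus Robotic
    Partial Nephrectomy for T1 Renal Cell Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A Markov cohort cost-utility model comparing percutaneous
    cryoablation (PCA) with robot-assisted partial nephrectomy (RAPN) for
    stage T1 renal cell carcinoma, together with the observational
    analysis pipeline that feeds it.  Provides a four-state monthly-cycle
    cohort engine with discounted cost and QALY accrual, incremental
    cost-effectiveness metrics (ICER, dominance, net monetary benefit),
    one-way deterministic sensitivity analysis with tornado ordering,
    calibration of metastatic mortality, an inverse-probability-of-
    treatment-weighting (IPTW) survival pipeline (propensity model,
    stabilized weights, balance diagnostics, weighted Cox and
    Kaplan-Meier), and a confounded synthetic-cohort generator for
    end-to-end testing without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
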