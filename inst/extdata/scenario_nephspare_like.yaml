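# SYNTHETIC cohort scenario emulating the published crude-population
# imbalance between cryoablation (PCA) and robotic partial nephrectomy
# (RAPN) arms: PCA patients older, with smaller tumors, more
# comorbidity, poorer renal function and worse performance status.
# This is a generative emulation, NOT patient data.  Covariate marginals
# are pooled targets; the propensity coefficients induce the arm-wise
# differences; event times are exponential at the base-case monthly
# probabilities (h0 = -log(1 - p_month)); administrative censoring is
# uniform on 18-42 months so median follow-up is about 30 months.
"n": 171
seed: 20190601
covariates:
  age: {mean: 64.7, sd: 11.7}
  sex_female: 0.27
  bmi: {mean: 29.2, sd: 5.8}
  egfr: {mean: 74.4, sd: 18.3}
  tumor_size: {mean: 34.1, sd: 11.3}
  asa_probs: {"0": 0.08, "1": 0.51, "2": 0.41}
  renal_probs: {"4": 0.105, "5": 0.064, "6": 0.146, "7": 0.211,
                "8": 0.199, "9": 0.170, "10": 0.099, "11": 0.006}
  ecog_probs: {"0": 0.71, "1": 0.20, "2": 0.08, "3": 0.01}
  cci_noise: 0.7
propensity:
  coef: {age: 0.045, tumor_size: -0.055, cci: 0.20, egfr: -0.015, ecog: 0.55}
  target_p_treated: 0.5321637
events:
  lr:
    h0: 0.0018016216
    coef: {tumor_size: 0.045, renal_score: 0.15}
    log_hr_treat: 0.0
  met:
    h0: 0.0035061397
    coef: {tumor_size: 0.05, renal_score: 0.12}
    log_hr_treat: 0.0
  death:
    h0: 0.0012007205
    coef: {age: 0.07, cci: 0.18}
    log_hr_treat: 0.0
complications: {PCA: 0.055, RAPN: 0.025}
los:
  pca_daycase_prob: 0.9340659
  pca_inpatient_mean: 3.0
  rapn_mean: 1.90
censoring: {min: 18, max: 42}
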