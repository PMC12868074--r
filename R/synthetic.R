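# run expr with a reproducible, locally scoped RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthetic confounded-cohort scenario
#'
#' Describes the generative model for a synthetic treatment cohort with
#' confounding by indication: covariates are drawn from marginal
#' distributions (with a monotone age-to-comorbidity link), treatment is
#' assigned by a logistic propensity model, and event times are
#' exponential with patient-specific log-linear hazards.  The defaults
#' emulate the observed cryoablation-vs-surgery imbalance: cryoablation
#' patients are older, with smaller tumors, more comorbidity, poorer
#' renal function and worse performance status.  Baseline monthly
#' hazards are `-log(1 - p_month)` at the base-case monthly event
#' probabilities; administrative censoring is uniform, calibrated so
#' median follow-up is about 30 months.
#'
#' @param n Default cohort size.
#' @param seed Default RNG seed.
#' @param covariates List of marginal covariate distributions (means/SDs
#'   for age, bmi, egfr, tumor_size; probabilities for sex_female,
#'   asa_probs, renal_probs, ecog_probs; `cci_noise` is the Poisson mean
#'   added to the age-derived comorbidity base).
#' @param propensity Named log-odds coefficients of treatment
#'   (cryoablation) per covariate unit, plus `target_p_treated`; the
#'   intercept is solved so the linear predictor at the covariate means
#'   hits the target marginal.
#' @param events List with `lr`, `met`, `death` sub-models, each
#'   `list(h0 =, coef =, log_hr_treat =)`: baseline monthly hazard,
#'   named log-hazard coefficients (applied to mean-centred covariates)
#'   and the true treatment log hazard ratio (0 = null effect).
#' @param complications Named per-arm complication probabilities.
#' @param los List with `pca_daycase_prob`, `pca_inpatient_mean`,
#'   `rapn_mean` (nights; day cases count as 1).
#' @param censoring `list(min =, max =)` months of uniform
#'   administrative censoring.
#' @return A `synthetic_scenario` object.
#' @export
synthetic_scenario <- function(
    n = 171, seed = 20190601,
    covariates = list(
      age = list(mean = 64.7, sd = 11.7),
      sex_female = 0.27,
      bmi = list(mean = 29.2, sd = 5.8),
      egfr = list(mean = 74.4, sd = 18.3),
      tumor_size = list(mean = 34.1, sd = 11.3),
      asa_probs = c(`0` = 0.08, `1` = 0.51, `2` = 0.41),
      renal_probs = c(`4` = 0.105, `5` = 0.064, `6` = 0.146, `7` = 0.211,
                      `8` = 0.199, `9` = 0.170, `10` = 0.099, `11` = 0.006),
      ecog_probs = c(`0` = 0.71, `1` = 0.20, `2` = 0.08, `3` = 0.01),
      cci_noise = 0.7),
    propensity = list(
      coef = c(age = 0.045, tumor_size = -0.055, cci = 0.20,
               egfr = -0.015, ecog = 0.55),
      target_p_treated = 91 / 171),
    events = list(
      lr = list(h0 = -log(1 - 0.0018),
                coef = c(tumor_size = 0.045, renal_score = 0.15),
                log_hr_treat = 0),
      met = list(h0 = -log(1 - 0.0035),
                 coef = c(tumor_size = 0.05, renal_score = 0.12),
                 log_hr_treat = 0),
      death = list(h0 = -log(1 - 0.0012),
                   coef = c(age = 0.07, cci = 0.18),
                   log_hr_treat = 0)),
    complications = c(PCA = 0.055, RAPN = 0.025),
    los = list(pca_daycase_prob = 85 / 91, pca_inpatient_mean = 3.0,
               rapn_mean = 1.90),
    censoring = list(min = 18, max = 42)) {
  stopifnot(n >= 1, all(complications >= 0 & complications <= 1),
            censoring$min > 0, censoring$max >= censoring$min)
  for (ev in events)
    if (ev$h0 < 0) stop_param("baseline hazards must be >= 0")
  structure(list(n = n, seed = seed, covariates = covariates,
                 propensity = propensity, events = events,
                 complications = complications, los = los,
                 censoring = censoring),
            class = "synthetic_scenario")
}

# population means used for hazard centring and the propensity intercept
scenario_centers <- function(scenario) {
  cv <- scenario$covariates
  cat_mean <- function(p) sum(as.numeric(names(p)) * p / sum(p))
  age_mean <- cv$age$mean
  c(age = age_mean,
    sex_female = cv$sex_female,
    bmi = cv$bmi$mean,
    egfr = cv$egfr$mean,
    tumor_size = cv$tumor_size$mean,
    asa = cat_mean(cv$asa_probs),
    renal_score = cat_mean(cv$renal_probs),
    ecog = cat_mean(cv$ecog_probs),
    cci = max(0, round((age_mean - 35) / 10) - 1) + cv$cci_noise)
}

#' Generate a synthetic cohort
#'
#' Pure function of `(scenario, seed)`: the same inputs reproduce the
#' same cohort exactly, and the global RNG state is left untouched.
#'
#' @param scenario A [synthetic_scenario()].
#' @param n Cohort size (defaults to the scenario's).
#' @param seed RNG seed (defaults to the scenario's).
#' @return Data frame with one row per patient: `id`, `arm`, the nine
#'   covariates, `time_lr`/`event_lr`, `time_met`/`event_met`
#'   (months, censored by death and administrative follow-up),
#'   `complication` and `los`.
#' @examples
#' co <- generate_cohort(synthetic_scenario(n = 200), seed = 1)
#' table(co$arm)
#' @export
generate_cohort <- function(scenario, n = scenario$n, seed = scenario$seed) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (n < 4) stop_param("'n' must be at least 4")
  cv <- scenario$covariates
  centers <- scenario_centers(scenario)
  with_seed(seed, {
    age <- stats::rnorm(n, cv$age$mean, cv$age$sd)
    sex <- ifelse(stats::runif(n) < cv$sex_female, "F", "M")
    bmi <- pmax(16, stats::rnorm(n, cv$bmi$mean, cv$bmi$sd))
    egfr <- pmax(5, stats::rnorm(n, cv$egfr$mean, cv$egfr$sd))
    tumor_size <- pmax(5, stats::rnorm(n, cv$tumor_size$mean, cv$tumor_size$sd))
    asa <- as.integer(sample(names(cv$asa_probs), n, TRUE, cv$asa_probs))
    renal_score <- as.integer(sample(names(cv$renal_probs), n, TRUE, cv$renal_probs))
    ecog <- as.integer(sample(names(cv$ecog_probs), n, TRUE, cv$ecog_probs))
    # monotone age -> comorbidity link plus independent noise
    cci <- pmax(0L, as.integer(round((age - 35) / 10) - 1L +
                                 stats::rpois(n, cv$cci_noise)))

    X <- cbind(age = age, sex_female = as.numeric(sex == "F"), bmi = bmi,
               egfr = egfr, tumor_size = tumor_size, asa = asa,
               renal_score = renal_score, ecog = ecog, cci = cci)

    beta <- scenario$propensity$coef
    intercept <- stats::qlogis(scenario$propensity$target_p_treated) -
      sum(beta * centers[names(beta)])
    lp <- intercept + as.numeric(X[, names(beta), drop = FALSE] %*% beta)
    p_pca <- stats::plogis(lp)
    if (all(p_pca > 1 - 1e-10) || all(p_pca < 1e-10))
      warning("degenerate scenario: one arm has probability ~1 for every patient")
    arm <- ifelse(stats::runif(n) < p_pca, "PCA", "RAPN")
    treat <- as.integer(arm == "PCA")

    draw_time <- function(model) {
      rate <- model$h0 * exp(
        as.numeric(X[, names(model$coef), drop = FALSE] %*% model$coef -
                     sum(model$coef * centers[names(model$coef)])) +
          model$log_hr_treat * treat)
      ifelse(rate > 0, stats::rexp(n, pmax(rate, 1e-300)), Inf)
    }
    t_lr <- draw_time(scenario$events$lr)
    t_met <- draw_time(scenario$events$met)
    t_death <- draw_time(scenario$events$death)
    cens <- stats::runif(n, scenario$censoring$min, scenario$censoring$max)

    time_lr <- pmin(t_lr, t_death, cens)
    event_lr <- as.integer(t_lr <= pmin(t_death, cens))
    time_met <- pmin(t_met, t_death, cens)
    event_met <- as.integer(t_met <= pmin(t_death, cens))

    complication <- stats::rbinom(n, 1, scenario$complications[arm])
    los <- numeric(n)
    pca <- arm == "PCA"
    daycase <- pca & stats::runif(n) < scenario$los$pca_daycase_prob
    # inpatient nights: 2 + Poisson keeps the configured mean with integer nights
    los[daycase] <- 1
    los[pca & !daycase] <- 2 + stats::rpois(sum(pca & !daycase),
                                            scenario$los$pca_inpatient_mean - 2)
    los[!pca] <- 1 + stats::rpois(sum(!pca), scenario$los$rapn_mean - 1)

    data.frame(id = seq_len(n), arm = arm, age = age, sex = sex, cci = cci,
               asa = asa, bmi = bmi, egfr = egfr, tumor_size = tumor_size,
               renal_score = renal_score, ecog = ecog,
               time_lr = time_lr, event_lr = event_lr,
               time_met = time_met, event_met = event_met,
               complication = complication, los = los)
  })
}

#' Closed-form event fraction for a covariate-free scenario
#'
#' For a scenario whose hazard coefficients are all zero, the
#' probability of an (uncensored) event within `months` in the baseline
#' arm is `1 - exp(-h0 * months)`.  Used to validate the generator
#' against the model's monthly event probabilities.
#'
#' @param scenario A [synthetic_scenario()] with zero covariate effects
#'   for the endpoint.
#' @param endpoint `"lr"`, `"met"` or `"death"`.
#' @param months Horizon in months, `>= 0`.
#' @return Event fraction in `[0, 1]`.
#' @export
expected_event_fraction <- function(scenario, endpoint = c("lr", "met", "death"),
                                    months) {
  stopifnot(inherits(scenario, "synthetic_scenario"), months >= 0)
  endpoint <- match.arg(endpoint)
  model <- scenario$events[[endpoint]]
  if (any(model$coef != 0))
    stop_param("closed form requires all hazard coefficients zero for '%s'",
               endpoint)
  1 - exp(-model$h0 * months)
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("Synthetic cohort scenario: n = %d, seed = %d\n", x$n, x$seed))
  cat(sprintf("  propensity coefficients: %s\n",
              paste(sprintf("%s=%.3g", names(x$propensity$coef),
                            x$propensity$coef), collapse = ", ")))
  cat(sprintf("  monthly hazards: LR %.5f, met %.5f, death %.5f; censoring U(%g, %g) mo\n",
              x$events$lr$h0, x$events$met$h0, x$events$death$h0,
              x$censoring$min, x$censoring$max))
  invisible(x)
}
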