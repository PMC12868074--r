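default_confounders <- c("age", "sex", "tumor_size", "renal_score", "ecog", "cci")

endpoint_cols <- function(endpoint) {
  switch(endpoint,
         local_recurrence = c(time = "time_lr", event = "event_lr"),
         metastasis = c(time = "time_met", event = "event_met"),
         stop_param("unknown endpoint '%s'", endpoint))
}

#' Fit the propensity model
#'
#' Maximum-likelihood logistic regression of treatment assignment on the
#' confounder set (default: age, sex, tumor size, RENAL score, ECOG
#' performance status and age-adjusted Charlson comorbidity index,
#' ordinal scores entered as integers).  Rows with missing covariates
#' are dropped (complete-case) with a message stating the count.
#' Stabilized weights are attached to the fit; see
#' [stabilized_weights()] for variants.
#'
#' @param cohort Data frame with one row per patient; must contain the
#'   treatment column and the covariates.
#' @param covariates Character vector of covariate column names.
#' @param treatment Treatment column name (default `"arm"`).
#' @param treated Level counted as treated (default `"PCA"`).
#' @return A `propensity_fit`: coefficients, fitted scores, stabilized
#'   weights, the complete-case data, and per-arm pseudo-population
#'   sizes (sums of weights).
#' @export
fit_propensity <- function(cohort, covariates = default_confounders,
                           treatment = "arm", treated = "PCA") {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(c(treatment, covariates), names(cohort))
  if (length(missing_cols))
    stop_param("cohort is missing columns: %s", paste(missing_cols, collapse = ", "))
  cc <- stats::complete.cases(cohort[, c(treatment, covariates)])
  if (any(!cc))
    message(sprintf("dropping %d of %d rows with missing covariates",
                    sum(!cc), nrow(cohort)))
  dat <- cohort[cc, , drop = FALSE]
  t_ind <- as.integer(dat[[treatment]] == treated)
  if (sum(t_ind) < 2 || sum(1 - t_ind) < 2)
    stop_param("need at least 2 patients per arm after complete-case filtering")

  mf <- dat[, covariates, drop = FALSE]
  fit <- stats::glm(t_ind ~ ., data = mf, family = stats::binomial())
  scores <- as.numeric(stats::fitted(fit))

  eps <- 1e-8
  if (any(scores < eps | scores > 1 - eps) || any(abs(stats::coef(fit)[-1]) > 15)) {
    sds <- vapply(mf, function(x) stats::sd(as.numeric(as.factor(x))), numeric(1))
    std_coef <- abs(stats::coef(fit)[-1])
    # match coefficients back to source columns (factors expand names)
    src <- covariates[vapply(names(std_coef), function(nm)
      which.max(startsWith(nm, covariates)), integer(1))]
    worst <- src[which.max(std_coef * sds[src])]
    stop_param("separation detected in the propensity model (covariate '%s')", worst)
  }
  if (!fit$converged)
    stop_param("propensity model did not converge in %d IRLS iterations", fit$iter)

  p_treated <- mean(t_ind)
  w <- ifelse(t_ind == 1, p_treated / scores, (1 - p_treated) / (1 - scores))
  structure(list(
    model = fit,
    coefficients = stats::coef(fit),
    scores = scores,
    treated = t_ind,
    p_treated = p_treated,
    weights = w,
    data = dat,
    treatment = treatment,
    treated_level = treated,
    pseudo_n = c(treated = sum(w[t_ind == 1]), control = sum(w[t_ind == 0])),
    n_dropped = sum(!cc)
  ), class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(sprintf("Propensity model: %d treated (%s) / %d control; %d rows dropped\n",
              sum(x$treated), x$treated_level, sum(1 - x$treated), x$n_dropped))
  cat(sprintf("Pseudo-population (stabilized): %.1f / %.1f\n",
              x$pseudo_n["treated"], x$pseudo_n["control"]))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Inverse-probability-of-treatment weights
#'
#' Stabilized weights are `P(treated)/score` for treated patients and
#' `(1 - P(treated))/(1 - score)` for controls, with the marginal
#' treated fraction estimated from the sample; they sum to roughly the
#' arm sizes.  The unstabilized variant (`1/score`, `1/(1 - score)`)
#' sums to roughly the total sample size per arm.
#'
#' @param fit A [fit_propensity()] result.
#' @param stabilized Logical, default `TRUE`.
#' @param trim Optional symmetric score-trimming bound (e.g. `0.01`
#'   clamps scores into `[0.01, 0.99]`, with a message stating how many
#'   were trimmed).  Without trimming, a score numerically 0 or 1 is an
#'   error.
#' @return Numeric weight vector aligned with `fit$data`.
#' @export
stabilized_weights <- function(fit, stabilized = TRUE, trim = NULL) {
  stopifnot(inherits(fit, "propensity_fit"))
  e <- fit$scores
  if (!is.null(trim)) {
    stopifnot(trim > 0, trim < 0.5)
    n_trim <- sum(e < trim | e > 1 - trim)
    if (n_trim) message(sprintf("trimming %d scores into [%g, %g]",
                                n_trim, trim, 1 - trim))
    e <- pmin(pmax(e, trim), 1 - trim)
  }
  if (any(e < 1e-10 | e > 1 - 1e-10))
    stop_param("propensity scores numerically 0 or 1; consider 'trim'")
  t_ind <- fit$treated
  num_t <- if (stabilized) fit$p_treated else 1
  num_c <- if (stabilized) 1 - fit$p_treated else 1
  ifelse(t_ind == 1, num_t / e, num_c / (1 - e))
}

weighted_mean_sd <- function(x, w) {
  m <- sum(w * x) / sum(w)
  v <- sum(w * (x - m)^2) / sum(w)  # population-style weighted variance
  c(mean = m, sd = sqrt(v))
}

effective_n <- function(w) sum(w)^2 / sum(w^2)

# Welch-type two-sample test on weighted means using effective sample sizes
weighted_t_p <- function(x1, w1, x0, w0) {
  s1 <- weighted_mean_sd(x1, w1); s0 <- weighted_mean_sd(x0, w0)
  n1 <- effective_n(w1); n0 <- effective_n(w0)
  se2 <- s1["sd"]^2 / n1 + s0["sd"]^2 / n0
  if (se2 == 0) return(1)
  t_stat <- (s1["mean"] - s0["mean"]) / sqrt(se2)
  df <- se2^2 / (s1["sd"]^4 / (n1^2 * (n1 - 1)) + s0["sd"]^4 / (n0^2 * (n0 - 1)))
  unname(2 * stats::pt(-abs(t_stat), df))
}

# chi-square-type test on weighted level proportions, scaled to ESS
weighted_chisq_p <- function(x1, w1, x0, w0) {
  lev <- sort(unique(c(x1, x0)))
  if (length(lev) < 2) return(1)
  p1 <- vapply(lev, function(l) sum(w1[x1 == l]) / sum(w1), numeric(1))
  p0 <- vapply(lev, function(l) sum(w0[x0 == l]) / sum(w0), numeric(1))
  n1 <- effective_n(w1); n0 <- effective_n(w0)
  obs <- rbind(p1 * n1, p0 * n0)
  keep <- colSums(obs) > 0
  obs <- obs[, keep, drop = FALSE]
  if (ncol(obs) < 2) return(1)
  exp_ <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  stat <- sum((obs - exp_)^2 / exp_)
  unname(stats::pchisq(stat, df = ncol(obs) - 1, lower.tail = FALSE))
}

smd_continuous <- function(x1, w1, x0, w0) {
  s1 <- weighted_mean_sd(x1, w1); s0 <- weighted_mean_sd(x0, w0)
  denom <- sqrt((s1["sd"]^2 + s0["sd"]^2) / 2)
  if (denom == 0) return(0)
  unname(abs(s1["mean"] - s0["mean"]) / denom)
}

# multi-level standardized difference (Yang & Dalton style Mahalanobis form)
smd_categorical <- function(x1, w1, x0, w0) {
  lev <- sort(unique(c(x1, x0)))
  if (length(lev) < 2) return(0)
  lev <- lev[-1]
  p1 <- vapply(lev, function(l) sum(w1[x1 == l]) / sum(w1), numeric(1))
  p0 <- vapply(lev, function(l) sum(w0[x0 == l]) / sum(w0), numeric(1))
  d <- p1 - p0
  pbar <- (p1 + p0) / 2
  S <- -outer(pbar, pbar); diag(S) <- pbar * (1 - pbar)
  inv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(inv)) return(max(abs(d)) / sqrt(max(pbar * (1 - pbar), 1e-12)))
  sqrt(max(0, as.numeric(t(d) %*% inv %*% d)))
}

#' Covariate balance before and after weighting
#'
#' For each covariate, reports per-arm summaries and p-values in the
#' crude population (unit weights) and the weighted pseudo-population,
#' plus crude and weighted standardized mean differences.  Numeric
#' covariates use weighted means/SDs and a Welch-type test on effective
#' sample sizes; categorical covariates use weighted proportions, a
#' chi-square-type test and the multi-level standardized difference.
#'
#' @param cohort Data frame aligned with `weights`.
#' @param weights Numeric IPTW weights.
#' @param covariates Covariate columns to tabulate.
#' @param treatment,treated Treatment column and treated level.
#' @return A data frame with one row per covariate (class
#'   `balance_table`).
#' @export
balance_table <- function(cohort, weights, covariates = default_confounders,
                          treatment = "arm", treated = "PCA") {
  stopifnot(is.data.frame(cohort), length(weights) == nrow(cohort),
            all(weights >= 0))
  t_ind <- cohort[[treatment]] == treated
  if (sum(weights[t_ind]) == 0 || sum(weights[!t_ind]) == 0)
    stop_param("zero total weight in one arm")
  rows <- lapply(covariates, function(cv) {
    x <- cohort[[cv]]
    num <- is.numeric(x)
    x1 <- x[t_ind]; x0 <- x[!t_ind]
    w1 <- weights[t_ind]; w0 <- weights[!t_ind]
    u1 <- rep(1, length(x1)); u0 <- rep(1, length(x0))
    if (num) {
      crude1 <- weighted_mean_sd(x1, u1); crude0 <- weighted_mean_sd(x0, u0)
      wt1 <- weighted_mean_sd(x1, w1); wt0 <- weighted_mean_sd(x0, w0)
      data.frame(covariate = cv, type = "continuous",
                 crude_treated = crude1["mean"], crude_control = crude0["mean"],
                 p_crude = weighted_t_p(x1, u1, x0, u0),
                 weighted_treated = wt1["mean"], weighted_control = wt0["mean"],
                 p_weighted = weighted_t_p(x1, w1, x0, w0),
                 smd_crude = smd_continuous(x1, u1, x0, u0),
                 smd_weighted = smd_continuous(x1, w1, x0, w0))
    } else {
      x1 <- as.character(x1); x0 <- as.character(x0)
      ref <- sort(unique(c(x1, x0)))[1]
      prop <- function(x, w) sum(w[x != ref]) / sum(w)
      data.frame(covariate = cv, type = "categorical",
                 crude_treated = prop(x1, u1), crude_control = prop(x0, u0),
                 p_crude = weighted_chisq_p(x1, u1, x0, u0),
                 weighted_treated = prop(x1, w1), weighted_control = prop(x0, w0),
                 p_weighted = weighted_chisq_p(x1, w1, x0, w0),
                 smd_crude = smd_categorical(x1, u1, x0, u0),
                 smd_weighted = smd_categorical(x1, w1, x0, w0))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("balance_table", "data.frame")
  out
}

#' Weighted Cox proportional hazards for the treatment effect
#'
#' Weighted Cox partial-likelihood fit of the single binary treatment
#' covariate (Breslow tie handling), with a robust sandwich variance
#' over patient-level score residuals — the naive information is invalid
#' under weighting.  The 95% CI is `exp(log_hr +/- 1.96 * robust_se)`.
#'
#' @param cohort Data frame with `time_lr`/`event_lr` and
#'   `time_met`/`event_met` columns.
#' @param weights IPTW weights aligned with `cohort` (unit weights give
#'   the ordinary unweighted fit).
#' @param endpoint `"local_recurrence"` or `"metastasis"`.
#' @param treatment,treated Treatment column and treated level; the
#'   hazard ratio is treated vs control.
#' @return A `cox_result` list: `log_hr`, `robust_se`, `hr`, `ci_low`,
#'   `ci_high`, `p_value`, `n_events`.
#' @export
weighted_cox <- function(cohort, weights, endpoint = c("local_recurrence", "metastasis"),
                         treatment = "arm", treated = "PCA") {
  endpoint <- match.arg(endpoint)
  cols <- endpoint_cols(endpoint)
  stopifnot(is.data.frame(cohort), length(weights) == nrow(cohort))
  time <- cohort[[cols["time"]]]
  event <- cohort[[cols["event"]]]
  if (any(time < 0) || !all(event %in% c(0, 1)))
    stop_param("invalid times or event indicators for endpoint '%s'", endpoint)
  if (sum(event) == 0) stop_param("no events for endpoint '%s'", endpoint)
  t_ind <- as.integer(cohort[[treatment]] == treated)
  if (sum(event[t_ind == 1]) == 0 || sum(event[t_ind == 0]) == 0)
    stop_param("all events in one arm: treatment log-hazard diverges")
  dat <- data.frame(time = time, event = event, treat = t_ind, .w = weights)
  fit <- survival::coxph(survival::Surv(time, event) ~ treat, data = dat,
                         weights = .w, robust = TRUE, ties = "breslow")
  log_hr <- unname(stats::coef(fit))
  if (!is.finite(log_hr) || abs(log_hr) > 15)
    stop_param("treatment log-hazard estimate diverged")
  rse <- sqrt(unname(fit$var[1, 1]))  # robust variance (sandwich)
  z <- log_hr / rse
  structure(list(
    endpoint = endpoint,
    log_hr = log_hr, robust_se = rse, hr = exp(log_hr),
    ci_low = exp(log_hr - 1.96 * rse), ci_high = exp(log_hr + 1.96 * rse),
    p_value = 2 * stats::pnorm(-abs(z)),
    n_events = sum(event), n = nrow(cohort)
  ), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("%s: HR = %.2f; 95%% CI = %.2f-%.2f; p = %.2f (%d events, robust SE %.3f)\n",
              x$endpoint, x$hr, x$ci_low, x$ci_high, x$p_value,
              x$n_events, x$robust_se))
  invisible(x)
}

#' Weighted Kaplan-Meier curves per arm
#'
#' Weighted product-limit estimate: at each event time the survival is
#' multiplied by `1 - sum(w_events)/sum(w_at_risk)` within each arm.
#'
#' @inheritParams weighted_cox
#' @return Data frame of `(time, survival, arm)` step-function points,
#'   including the `(0, 1)` anchor per arm.
#' @export
weighted_km <- function(cohort, weights, endpoint = c("local_recurrence", "metastasis"),
                        treatment = "arm") {
  endpoint <- match.arg(endpoint)
  cols <- endpoint_cols(endpoint)
  stopifnot(length(weights) == nrow(cohort), all(weights >= 0))
  dat <- data.frame(time = cohort[[cols["time"]]],
                    event = cohort[[cols["event"]]],
                    arm = as.character(cohort[[treatment]]), .w = weights)
  out <- do.call(rbind, lapply(split(dat, dat$arm), function(d) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d,
                             weights = .w)
    data.frame(time = c(0, fit$time), survival = c(1, fit$surv),
               arm = d$arm[1])
  }))
  rownames(out) <- NULL
  out
}

#' Pooled two-proportion z-test
#'
#' Compares two binomial proportions with the pooled-variance z
#' statistic; the two-sided p-value comes from the standard normal.
#' Equivalent to the chi-square test without continuity correction
#' (`z^2` is the X-squared statistic).
#'
#' @param x1,n1 Events and size of group 1.
#' @param x2,n2 Events and size of group 2.
#' @return List with `z`, `p_value`, `p1`, `p2`.
#' @examples
#' compare_proportions(5, 91, 2, 80)  # p ~ 0.325
#' @export
compare_proportions <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) stop_param("group sizes must be >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop_param("event counts must satisfy 0 <= x <= n")
  p1 <- x1 / n1; p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}
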