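null_scenario <- function() {
  synthetic_scenario(
    propensity = list(coef = c(age = 0), target_p_treated = 0.5),
    events = list(
      lr = list(h0 = 0.0018, coef = c(tumor_size = 0), log_hr_treat = 0),
      met = list(h0 = 0.0035, coef = c(tumor_size = 0), log_hr_treat = 0),
      death = list(h0 = 0.0012, coef = c(age = 0), log_hr_treat = 0)))
}

fake_fit <- function(scores, treated, p_treated = mean(treated)) {
  structure(list(scores = scores, treated = treated, p_treated = p_treated),
            class = "propensity_fit")
}

test_that("propensity slopes vanish when treatment ignores covariates", {
  co <- generate_cohort(null_scenario(), n = 5000, seed = 101)
  fit <- fit_propensity(co)
  cf <- summary(fit$model)$coefficients
  slopes <- cf[-1, , drop = FALSE]
  expect_true(all(abs(slopes[, "Estimate"]) < 3 * slopes[, "Std. Error"]))
})

test_that("a single binary covariate recovers the contingency-table odds ratio", {
  co <- data.frame(
    arm = rep(c("PCA", "RAPN"), each = 50),
    exposed = c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40)))
  fit <- fit_propensity(co, covariates = "exposed")
  or_table <- (30 / 20) / (10 / 40)
  expect_equal(unname(exp(fit$coefficients["exposed"])), or_table,
               tolerance = 1e-6)
})

test_that("perfect separation raises an error naming the covariate", {
  co <- data.frame(arm = rep(c("PCA", "RAPN"), each = 20),
                   age = c(70 + 1:20, 40 + 1:20))
  expect_error(suppressWarnings(fit_propensity(co, covariates = "age")), "age")
})

test_that("rows with missing covariates are dropped with a count", {
  co <- generate_cohort(synthetic_scenario(), n = 200, seed = 5)
  co$age[c(3, 9, 33)] <- NA
  expect_message(fit <- fit_propensity(co), "3 of 200")
  expect_equal(nrow(fit$data), 197)
})

test_that("scores at the marginal give unit stabilized weights", {
  fit <- fake_fit(scores = rep(0.4, 10),
                  treated = rep(c(1, 0), 5), p_treated = 0.4)
  expect_equal(stabilized_weights(fit), rep(1, 10))
})

test_that("the 4-patient toy reproduces hand-computed weights", {
  fit <- fake_fit(scores = c(0.8, 0.4, 0.5, 0.2),
                  treated = c(1, 1, 0, 0), p_treated = 0.5)
  expect_equal(stabilized_weights(fit), c(0.625, 1.25, 1.0, 0.625))
  expect_equal(stabilized_weights(fit, stabilized = FALSE),
               c(1 / 0.8, 1 / 0.4, 1 / 0.5, 1 / 0.8))
})

test_that("per-arm mean stabilized weight approaches 1 in a large cohort", {
  co <- generate_cohort(synthetic_scenario(), n = 10000, seed = 77)
  fit <- fit_propensity(co)
  w <- stabilized_weights(fit)
  t_ind <- fit$treated
  expect_equal(mean(w[t_ind == 1]), 1, tolerance = 0.05)
  expect_equal(mean(w[t_ind == 0]), 1, tolerance = 0.05)
  # unstabilized weights scale the pseudo-population to ~ total n per arm
  wu <- stabilized_weights(fit, stabilized = FALSE)
  expect_equal(sum(wu[t_ind == 1]) / nrow(co), 1, tolerance = 0.1)
})

test_that("degenerate scores error without trimming and trim with it", {
  fit <- fake_fit(scores = c(1e-12, 0.5, 0.5, 0.9),
                  treated = c(0, 1, 0, 1), p_treated = 0.5)
  expect_error(stabilized_weights(fit), "trim")
  expect_message(w <- stabilized_weights(fit, trim = 0.01), "trimming 1")
  expect_true(all(is.finite(w)))
})

test_that("identical duplicated arms are perfectly balanced", {
  half <- generate_cohort(synthetic_scenario(), n = 100, seed = 3)
  half$arm <- "PCA"
  other <- half; other$arm <- "RAPN"
  co <- rbind(half, other)
  bal <- balance_table(co, rep(1, nrow(co)))
  expect_true(all(bal$smd_crude < 1e-12))
  expect_true(all(bal$smd_weighted < 1e-12))
  expect_true(all(bal$p_crude > 1 - 1e-9))
  expect_true(all(bal$p_weighted > 1 - 1e-9))
})

test_that("unit weights reduce weighted summaries to crude ones", {
  co <- generate_cohort(synthetic_scenario(), n = 400, seed = 13)
  bal <- balance_table(co, rep(1, nrow(co)))
  expect_equal(bal$weighted_treated, bal$crude_treated)
  expect_equal(bal$p_weighted, bal$p_crude)
  expect_equal(bal$smd_weighted, bal$smd_crude)
  # weighted mean equals the plain mean
  expect_equal(bal$crude_treated[bal$covariate == "age"],
               mean(co$age[co$arm == "PCA"]))
})

test_that("weighting removes the built-in confounding imbalance", {
  co <- generate_cohort(synthetic_scenario(), n = 2000, seed = 2020)
  fit <- fit_propensity(co)
  w <- stabilized_weights(fit)
  bal <- balance_table(fit$data, w)
  expect_gt(max(bal$smd_crude), 0.25)
  expect_true(all(bal$smd_weighted < 0.1))
})

test_that("zero weight in an arm is an error", {
  co <- generate_cohort(synthetic_scenario(), n = 50, seed = 1)
  w <- ifelse(co$arm == "PCA", 0, 1)
  expect_error(balance_table(co, w), "zero total weight")
})

test_that("identical event-time lists give a unit hazard ratio", {
  times <- c(2, 5, 9, 14, 20)
  co <- data.frame(arm = rep(c("PCA", "RAPN"), each = 5),
                   time_lr = rep(times, 2), event_lr = 1,
                   time_met = rep(times, 2), event_met = 1)
  res <- weighted_cox(co, rep(1, 10), "local_recurrence")
  expect_equal(res$hr, 1, tolerance = 1e-8)
  expect_true(res$ci_low <= 1 && res$ci_high >= 1)
})

test_that("the weighted Cox log-HR maximizes the Breslow partial likelihood", {
  co <- cox_toy()
  for (ep in c("local_recurrence", "metastasis")) {
    cols <- if (ep == "local_recurrence") c("time_lr", "event_lr")
            else c("time_met", "event_met")
    res <- weighted_cox(co, rep(1, 8), ep)
    brute <- stats::optimize(function(b)
      breslow_loglik(b, co[[cols[1]]], co[[cols[2]]],
                     as.integer(co$arm == "PCA")),
      interval = c(-5, 5), maximum = TRUE, tol = 1e-9)$maximum
    expect_equal(res$log_hr, brute, tolerance = 1e-4)
  }
})

test_that("weighted Cox at non-unit weights still maximizes the weighted likelihood", {
  co <- cox_toy()
  w <- c(0.5, 1.5, 1, 2, 0.8, 1.2, 1, 0.7)
  res <- weighted_cox(co, w, "local_recurrence")
  brute <- stats::optimize(function(b)
    breslow_loglik(b, co$time_lr, co$event_lr,
                   as.integer(co$arm == "PCA"), weights = w),
    interval = c(-5, 5), maximum = TRUE, tol = 1e-9)$maximum
  expect_equal(res$log_hr, brute, tolerance = 1e-4)
})

test_that("event-free and single-arm-event inputs are rejected", {
  co <- cox_toy()
  co$event_lr <- 0
  expect_error(weighted_cox(co, rep(1, 8), "local_recurrence"), "no events")
  co$event_lr <- c(1, 1, 1, 1, 0, 0, 0, 0)  # all events in PCA
  expect_error(weighted_cox(co, rep(1, 8), "local_recurrence"), "one arm")
})

test_that("weighted KM reduces to the hand product-limit at unit weights", {
  co <- data.frame(arm = "PCA",
                   time_lr = c(1, 3, 4, 7, 9), event_lr = c(1, 0, 1, 1, 0),
                   time_met = 1, event_met = 0)
  km <- weighted_km(co, rep(1, 5), "local_recurrence")
  # hand product-limit: events at t=1 (5 at risk), t=4 (3), t=7 (2)
  hand <- c(1, 4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2)
  surv_at <- function(t) km$survival[max(which(km$time <= t))]
  expect_equal(surv_at(0), 1)
  expect_equal(surv_at(1), hand[2])
  expect_equal(surv_at(4), hand[3])
  expect_equal(surv_at(7), hand[4])
})

test_that("KM curves are flat without events and non-increasing in general", {
  co <- data.frame(arm = rep(c("PCA", "RAPN"), 5),
                   time_lr = 1:10, event_lr = 0,
                   time_met = 1:10, event_met = 0)
  km <- weighted_km(co, rep(1, 10), "local_recurrence")
  expect_true(all(km$survival == 1))
  set.seed(9)
  for (i in 1:5) {
    co <- generate_cohort(synthetic_scenario(), n = 120, seed = i)
    w <- stabilized_weights(fit_propensity(co))
    km <- weighted_km(co, w, "metastasis")
    for (a in unique(km$arm))
      expect_true(all(diff(km$survival[km$arm == a]) <= 1e-12))
  }
})

test_that("the pooled z-test behaves at its boundary and symmetry cases", {
  eq <- compare_proportions(5, 50, 5, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  a <- compare_proportions(5, 91, 2, 80)
  b <- compare_proportions(2, 80, 5, 91)
  expect_equal(a$z, -b$z)
  expect_equal(a$p_value, b$p_value)
  # cross-check against the uncorrected chi-square (z^2 = X-squared)
  ct <- suppressWarnings(stats::prop.test(c(5, 2), c(91, 80), correct = FALSE))
  expect_equal(a$z^2, unname(ct$statistic), tolerance = 1e-9)
  expect_equal(a$p_value, ct$p.value, tolerance = 1e-9)
  expect_error(compare_proportions(1, 0, 1, 10), ">= 1")
})
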