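test_that("null hazards give the identity matrix and a frozen cohort", {
  sh <- null_shared()
  M <- build_transition_matrix(sh)
  expect_equal(unname(M), diag(4))
  tr <- run_cohort(pca_strategy(), sh)
  expect_true(all(tr$stable == 1))
  expect_true(all(tr[, c("local_recurrence", "metastatic", "dead")] == 0))
})

test_that("base-case stable row carries the monthly event probabilities", {
  M <- build_transition_matrix(basecase()$shared)
  expect_equal(unname(M["stable", -1]), c(0.0018, 0.0035, 0.0012))
  expect_equal(M["stable", "stable"], 1 - 0.0018 - 0.0035 - 0.0012)
  expect_equal(unname(M["dead", ]), c(0, 0, 0, 1))
})

test_that("every transition row sums to 1 over random parameter draws", {
  set.seed(42)
  for (i in 1:1000) {
    M <- build_transition_matrix(random_shared())
    expect_true(all(abs(rowSums(M) - 1) < 1e-12))
    expect_true(all(M >= 0 & M <= 1))
  }
})

test_that("invalid row probabilities raise an error naming the row", {
  sh <- shared_params()
  bad <- pca_strategy(p_metastasis = 0.95)
  sh$p_background_death <- 0.1
  expect_error(build_transition_matrix(sh, strategy = bad), "stable")
})

test_that("time-homogeneous traces equal matrix powers", {
  set.seed(7)
  for (i in 1:5) {
    sh <- random_shared()
    tr <- run_cohort(pca_strategy(), sh)
    M <- build_transition_matrix(sh)
    v <- c(1, 0, 0, 0)
    P <- diag(4)
    for (t in 1:60) {
      P <- P %*% M
      if (t %in% c(1, 12, 60)) {
        expect_lt(max(abs(as.numeric(tr[t + 1, markov_states]) -
                            as.numeric(v %*% P))), 1e-10)
      }
    }
  }
})

test_that("dead occupancy matches an independent step-by-step recomputation", {
  sh <- basecase()$shared
  tr <- run_cohort(rapn_strategy(), sh)
  # brute-force per-cycle simulation, written without the engine's matrix
  s <- 1; lr <- 0; met <- 0; dead <- 0
  p_lr <- 0.0018; p_m <- 0.0035; p_bg <- 0.0012
  p_ms <- sh$met_mortality$p_month
  for (t in 1:60) {
    d_met <- 1 - (1 - p_bg) * (1 - p_ms)
    new_dead <- dead + s * p_bg + lr * p_bg + met * d_met
    new_met <- met * (1 - d_met) + s * p_m + lr * p_m
    new_lr <- lr * (1 - p_m - p_bg) + s * p_lr
    new_s <- s * (1 - p_lr - p_m - p_bg)
    s <- new_s; lr <- new_lr; met <- new_met; dead <- new_dead
  }
  expect_equal(tr$dead[61], dead, tolerance = 1e-12)
  expect_equal(tr$stable[61], s, tolerance = 1e-12)
})

test_that("occupancy is conserved and death is monotone", {
  set.seed(11)
  for (i in 1:25) {
    tr <- run_cohort(pca_strategy(), random_shared())
    expect_true(all(abs(rowSums(tr[, markov_states]) - 1) < 1e-9))
    expect_true(all(diff(tr$dead) >= -1e-12))
  }
})

test_that("discount factor follows the annual convention", {
  expect_identical(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(12, 0.03), 1 / 1.03)
  expect_equal(discount_factor(60, 0.03), 1.03^-5)
  expect_error(discount_factor(12, -0.01), "non-negative")
  expect_error(discount_factor(-1, 0.03))
})

test_that("procedure-month accrual isolates the intervention QALY", {
  sh <- shared_params()
  free <- strategy_params("ghost", c_procedure = 0, p_complication = 0)
  tr <- degenerate_trace("dead", sh$horizon_cycles)
  out <- accrue_outcomes(tr, free, sh)
  expect_equal(out$qaly_discounted, 0.058)
  expect_equal(out$cost_discounted, 0)
})

test_that("undiscounted null-hazard QALY has the closed form", {
  sh <- null_shared(discount_annual = 0)
  free <- strategy_params("ghost", c_procedure = 0, p_complication = 0)
  out <- run_strategy(free, sh)
  expect_equal(out$qaly_discounted, 0.058 + 59 * 0.76 / 12)
  expect_equal(out$qaly_discounted, out$qaly_undiscounted)
})

test_that("base-case accrual matches a row-by-row spreadsheet recomputation", {
  prm <- basecase()
  sh <- prm$shared
  strat <- prm$strategies$RAPN
  out <- run_strategy(strat, sh)
  tr <- out$trace
  cost <- strat$c_procedure + strat$p_complication * sh$c_complication +
    sh$c_bed_night * strat$mean_los
  qaly <- sh$q_intervention_month - strat$p_complication * sh$du_complication
  for (m in 1:59) {
    disc <- 1.03^(-m / 12)
    qaly <- qaly + disc * (0.76 * tr$stable[m + 1] +
                             0.70 * tr$local_recurrence[m + 1] +
                             0.66 * tr$metastatic[m + 1]) / 12
    cost <- cost + disc * 2500 * tr$metastatic[m + 1]
  }
  expect_equal(out$cost_discounted, cost, tolerance = 1e-12)
  expect_equal(out$qaly_discounted, qaly, tolerance = 1e-12)
})

test_that("discounted totals never exceed undiscounted and obey the QALY bound", {
  set.seed(3)
  for (i in 1:10) {
    sh <- random_shared()
    out <- run_strategy(pca_strategy(), sh)
    expect_lte(out$cost_discounted, out$cost_undiscounted + 1e-9)
    expect_lte(out$qaly_discounted, out$qaly_undiscounted + 1e-9)
    bound <- 0.058 + sum((sh$u_stable / 12) *
                           (1 + sh$discount_annual)^(-(1:59) / 12))
    expect_lte(out$qaly_discounted, bound + 1e-9)
  }
})

test_that("raising a death probability never lowers final dead occupancy", {
  sh <- basecase()$shared
  base_dead <- tail(run_cohort(pca_strategy(), sh)$dead, 1)
  sh_hi <- sh; sh_hi$p_background_death <- sh$p_background_death * 2
  expect_gte(tail(run_cohort(pca_strategy(), sh_hi)$dead, 1), base_dead)
  sh_ms <- sh
  sh_ms$met_mortality <- met_survival_spec("exponential",
                                           p_month = 2 * sh$met_mortality$p_month)
  expect_gte(tail(run_cohort(pca_strategy(), sh_ms)$dead, 1), base_dead)
})

test_that("trace/parameter horizon mismatch is an error", {
  sh <- shared_params()
  tr <- run_cohort(pca_strategy(), sh)
  sh$horizon_cycles <- 48L
  expect_error(accrue_outcomes(tr, pca_strategy(), sh), "horizon")
})

test_that("weibull metastatic mortality yields a valid non-increasing survival", {
  spec <- met_survival_spec("weibull", shape = 1.3, scale = 30)
  p <- p_met_month(spec, 0:59)
  expect_true(all(p >= 0 & p <= 1))
  S <- cumprod(1 - p)
  expect_true(all(diff(S) <= 0))
  sh <- shared_params(met_mortality = spec)
  tr <- run_cohort(pca_strategy(), sh)
  expect_true(all(abs(rowSums(tr[, markov_states]) - 1) < 1e-9))
})

test_that("half-cycle correction changes accrual but conserves structure", {
  prm <- basecase()
  sh_hcc <- prm$shared; sh_hcc$half_cycle_correction <- TRUE
  out <- run_strategy(prm$strategies$PCA, prm$shared)
  out_hcc <- run_strategy(prm$strategies$PCA, sh_hcc)
  expect_false(isTRUE(all.equal(out$qaly_discounted, out_hcc$qaly_discounted)))
  # ~0.058/2 QALY scale difference at most for monthly cycles
  expect_lt(abs(out$qaly_discounted - out_hcc$qaly_discounted), 0.01)
})

test_that("survival-anchored calibration recovers the exponential closed form", {
  spec <- calibrate_metastatic_mortality(shared_params(),
    list(type = "survival", fraction = 0.25, month = 60))
  expect_equal(spec$p_month, 1 - 0.25^(1 / 60), tolerance = 1e-5)
})

test_that("outcome-anchored calibration reproduces its target when rerun", {
  prm <- basecase()
  target <- 3.26
  spec <- calibrate_metastatic_mortality(prm$shared,
    list(type = "outcome", strategy = prm$strategies$RAPN,
         component = "qaly_discounted", target = target))
  sh <- prm$shared; sh$met_mortality <- spec
  expect_equal(run_strategy(prm$strategies$RAPN, sh)$qaly_discounted,
               target, tolerance = 1e-6)
})

test_that("unreachable calibration anchors are infeasible, not silent", {
  prm <- basecase()
  sh0 <- prm$shared
  sh0$met_mortality <- met_survival_spec("exponential", p_month = 0)
  upper <- run_strategy(prm$strategies$RAPN, sh0)$qaly_discounted
  expect_error(
    calibrate_metastatic_mortality(prm$shared,
      list(type = "outcome", strategy = prm$strategies$RAPN,
           component = "qaly_discounted", target = upper + 0.1)),
    "infeasible")
})
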