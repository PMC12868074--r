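#' Discount factor for a monthly cycle
#'
#' Costs and QALYs are discounted at an annual rate; the factor applied
#' to cycle `m` (months) is `(1 + annual_rate)^(-m/12)`, so cycle 0 is
#' undiscounted and cycle 12 is one full year of discounting.
#'
#' @param cycle Month index, `>= 0` (vectorised).
#' @param annual_rate Annual discount rate, `>= 0`.
#' @return Multiplier in `(0, 1]`.
#' @examples
#' discount_factor(12, 0.03)  # 1/1.03
#' @export
discount_factor <- function(cycle, annual_rate) {
  if (any(cycle < 0)) stop_param("'cycle' must be >= 0")
  if (!is.numeric(annual_rate) || length(annual_rate) != 1L || annual_rate < 0)
    stop_param("'annual_rate' must be a single non-negative number")
  (1 + annual_rate)^(-cycle / 12)
}

strategy_prob <- function(strategy, shared, field) {
  if (!is.null(strategy) && !is.null(strategy[[field]])) strategy[[field]]
  else shared[[field]]
}

#' Per-cycle transition matrix
#'
#' Builds the 4x4 transition matrix of the cohort model for one cycle.
#' From stable disease the cohort may recur locally, progress to
#' metastatic disease or die of background causes; from local recurrence
#' it may progress or die; in the metastatic state background and
#' metastatic mortality act as independent competing risks, giving a
#' death probability `1 - (1 - p_bg) * (1 - p_met_death)`; death is
#' absorbing.
#'
#' @param shared A [shared_params()] object.
#' @param cycle Cycle index in `[0, horizon)`; only matters for
#'   time-varying (Weibull) metastatic mortality.
#' @param strategy Optional [strategy_params()] whose event-probability
#'   overrides, if set, replace the shared values.
#' @return A 4x4 matrix with `markov_states` dimnames; every row sums
#'   to 1.
#' @examples
#' M <- build_transition_matrix(shared_params())
#' rowSums(M)
#' @export
build_transition_matrix <- function(shared, cycle = 0, strategy = NULL) {
  stopifnot(inherits(shared, "shared_params"))
  if (cycle < 0 || cycle >= shared$horizon_cycles)
    stop_param("'cycle' must lie in [0, horizon_cycles)")
  p_lr <- strategy_prob(strategy, shared, "p_local_recurrence")
  p_ms <- strategy_prob(strategy, shared, "p_metastasis")
  p_bg <- shared$p_background_death
  p_md <- p_met_month(shared$met_mortality, cycle)

  stay_stable <- 1 - p_lr - p_ms - p_bg
  if (stay_stable < 0)
    stop_param("invalid parameters: probabilities out of 'stable' exceed 1")
  stay_lr <- 1 - p_ms - p_bg
  if (stay_lr < 0)
    stop_param("invalid parameters: probabilities out of 'local_recurrence' exceed 1")
  p_die_met <- 1 - (1 - p_bg) * (1 - p_md)

  M <- rbind(c(stay_stable, p_lr, p_ms, p_bg),
             c(0, stay_lr, p_ms, p_bg),
             c(0, 0, 1 - p_die_met, p_die_met),
             c(0, 0, 0, 1))
  dimnames(M) <- list(markov_states, markov_states)
  M
}

#' Run the cohort through the model
#'
#' Starts the whole cohort in stable disease at cycle 0 (the procedure
#' month) and advances it one monthly cycle at a time: the occupancy row
#' at cycle `t` is the cycle `t-1` row multiplied by the cycle `t-1`
#' transition matrix.
#'
#' @param strategy A [strategy_params()] object.
#' @param shared A [shared_params()] object.
#' @return A `cohort_trace` data frame with columns `cycle` (0 to
#'   horizon) and one occupancy column per state; rows sum to 1.
#' @examples
#' tr <- run_cohort(strategy_params("PCA", 7427, 0.055, 1.13), shared_params())
#' tail(tr, 2)
#' @export
run_cohort <- function(strategy, shared) {
  stopifnot(inherits(strategy, "strategy_params"), inherits(shared, "shared_params"))
  H <- shared$horizon_cycles
  occ <- matrix(0, H + 1, 4, dimnames = list(NULL, markov_states))
  occ[1, ] <- c(1, 0, 0, 0)
  time_varying <- shared$met_mortality$family != "exponential"
  M <- build_transition_matrix(shared, 0, strategy)
  for (t in seq_len(H)) {
    if (time_varying && t > 1)
      M <- build_transition_matrix(shared, t - 1, strategy)
    occ[t + 1, ] <- occ[t, ] %*% M
  }
  out <- data.frame(cycle = 0:H, occ)
  class(out) <- c("cohort_trace", "data.frame")
  attr(out, "strategy") <- strategy$name
  attr(out, "horizon_cycles") <- H
  out
}

#' Accrue discounted costs and QALYs along a trace
#'
#' Cycle 0 is the procedure month: it accrues the procedure cost, the
#' expected complication cost (`p_complication * c_complication`), any
#' bed-night cost (`c_bed_night * mean_los`), the fixed
#' intervention-month QALY and the expected complication disutility
#' (`p_complication * du_complication`), all undiscounted.  Cycles
#' `m = 1 ... horizon-1` accrue state utilities at `utility/12` and the
#' per-state monthly costs weighted by occupancy, multiplied by
#' [discount_factor()].
#'
#' @param trace A `cohort_trace` from [run_cohort()] under the same
#'   parameters.
#' @param strategy,shared The parameter objects used to build the trace.
#' @return An `arm_outcome` list: discounted and undiscounted totals, the
#'   trace, and a per-cycle accrual table (`cycles`).
#' @export
accrue_outcomes <- function(trace, strategy, shared) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(strategy, "strategy_params"),
            inherits(shared, "shared_params"))
  H <- shared$horizon_cycles
  if (nrow(trace) != H + 1)
    stop_param("trace has %d rows but horizon_cycles = %d implies %d",
               nrow(trace), H, H + 1)

  occ <- as.matrix(trace[, markov_states])
  if (shared$half_cycle_correction) {
    # mid-cycle occupancy for accrual cycles 1..H-1
    occ_acc <- (occ[1:H, ] + occ[2:(H + 1), ]) / 2
  } else {
    occ_acc <- occ[1:H, , drop = FALSE]  # occupancy at cycle m, m = 0..H-1
  }

  m <- 1:(H - 1)
  disc <- discount_factor(m, shared$discount_annual)
  u_month <- c(shared$u_stable, shared$u_local_recurrence, shared$u_metastatic, 0) / 12
  c_month <- c(0, shared$c_local_recurrence_monthly, shared$c_advanced_monthly, 0)

  qaly_state <- as.numeric(occ_acc[m + 1, , drop = FALSE] %*% u_month)
  cost_state <- as.numeric(occ_acc[m + 1, , drop = FALSE] %*% c_month)

  q0 <- shared$q_intervention_month - strategy$p_complication * shared$du_complication
  c0 <- strategy$c_procedure + strategy$p_complication * shared$c_complication +
    shared$c_bed_night * strategy$mean_los

  cycles <- data.frame(
    cycle = 0:H,
    trace[, markov_states],
    cost_cycle = c(c0, cost_state, 0),
    qaly_cycle = c(q0, qaly_state, 0),
    discount_factor = c(1, disc, discount_factor(H, shared$discount_annual))
  )
  structure(list(
    strategy = strategy$name,
    cost_discounted = c0 + sum(disc * cost_state),
    qaly_discounted = q0 + sum(disc * qaly_state),
    cost_undiscounted = c0 + sum(cost_state),
    qaly_undiscounted = q0 + sum(qaly_state),
    trace = trace,
    cycles = cycles,
    horizon_cycles = H,
    discount_annual = shared$discount_annual,
    wtp = shared$wtp
  ), class = "arm_outcome")
}

#' Run one strategy end to end
#'
#' Convenience wrapper: [run_cohort()] followed by [accrue_outcomes()].
#'
#' @inheritParams run_cohort
#' @return An `arm_outcome`.
#' @examples
#' out <- run_strategy(strategy_params("RAPN", 15293, 0.025, 1.90),
#'                     shared_params())
#' out$qaly_discounted
#' @export
run_strategy <- function(strategy, shared) {
  accrue_outcomes(run_cohort(strategy, shared), strategy, shared)
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("Arm %s over %d monthly cycles (discount %.1f%%/yr)\n",
              x$strategy, x$horizon_cycles, 100 * x$discount_annual))
  cat(sprintf("  discounted:   %10.2f EUR  %7.3f QALYs\n",
              x$cost_discounted, x$qaly_discounted))
  cat(sprintf("  undiscounted: %10.2f EUR  %7.3f QALYs\n",
              x$cost_undiscounted, x$qaly_undiscounted))
  invisible(x)
}

#' Calibrate exponential metastatic mortality to an anchor
#'
#' The metastatic survival curve is cited but not printed in the source
#' tariffs, so the monthly metastatic death probability can be
#' recalibrated to an external anchor by monotone bisection on `[0, 1]`.
#' Two anchors are supported: a metastatic survival fraction at a stated
#' month (`(1 - p)^month = fraction` for the exponential family), or a
#' target discounted outcome component for a named strategy.
#'
#' @param shared A [shared_params()]; its `met_mortality` is replaced by
#'   the calibrated spec in the returned function's model runs.
#' @param anchor A list. Either `list(type = "survival", fraction =, month =)`
#'   or `list(type = "outcome", strategy =, component =, target =)` where
#'   `component` is one of `"qaly_discounted"`, `"cost_discounted"` and
#'   `strategy` is a [strategy_params()].
#' @param tol Relative tolerance on the anchored quantity (default 1e-6).
#' @param max_iter Maximum bisection iterations (default 200).
#' @return The calibrated [met_survival_spec()] (exponential).
#' @examples
#' calibrate_metastatic_mortality(shared_params(),
#'   list(type = "survival", fraction = 0.10, month = 60))
#' @export
calibrate_metastatic_mortality <- function(shared, anchor,
                                           tol = 1e-6, max_iter = 200) {
  stopifnot(inherits(shared, "shared_params"), is.list(anchor))
  type <- anchor$type %||% stop_param("anchor needs a 'type'")
  if (type == "survival") {
    frac <- anchor$fraction; mon <- anchor$month
    if (is.null(frac) || is.null(mon) || frac <= 0 || frac > 1 || mon < 1)
      stop_param("survival anchor needs fraction in (0, 1] and month >= 1")
    f <- function(p) (1 - p)^mon - frac
    target <- frac
  } else if (type == "outcome") {
    strategy <- anchor$strategy
    component <- anchor$component %||% "qaly_discounted"
    target <- anchor$target
    if (!inherits(strategy, "strategy_params") || is.null(target))
      stop_param("outcome anchor needs a strategy_params and a numeric target")
    if (!component %in% c("qaly_discounted", "cost_discounted"))
      stop_param("anchor component must be qaly_discounted or cost_discounted")
    f <- function(p) {
      shared$met_mortality <- met_survival_spec("exponential", p_month = p)
      run_strategy(strategy, shared)[[component]] - target
    }
  } else stop_param("unknown anchor type '%s'", type)

  lo <- 0; hi <- 1
  f_lo <- f(lo); f_hi <- f(hi)
  if (is.na(f_lo) || is.na(f_hi) || sign(f_lo) == sign(f_hi))
    stop_param("calibration infeasible: anchor not bracketed by p in [0, 1]")
  p <- NA_real_
  for (i in seq_len(max_iter)) {
    p <- (lo + hi) / 2
    f_p <- f(p)
    if (abs(f_p) <= tol * max(abs(target), .Machine$double.eps)) break
    if (sign(f_p) == sign(f_lo)) { lo <- p; f_lo <- f_p } else hi <- p
    if (i == max_iter)
      stop_param("calibration failed to converge within %d iterations", max_iter)
  }
  met_survival_spec("exponential", p_month = p)
}

#' Write a cohort accrual trace to CSV
#'
#' Exports the per-cycle table of an `arm_outcome` (occupancies, cycle
#' cost, cycle QALY, discount factor) as a plain CSV.
#'
#' @param outcome An `arm_outcome` from [run_strategy()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(outcome, path) {
  stopifnot(inherits(outcome, "arm_outcome"))
  utils::write.csv(outcome$cycles, path, row.names = FALSE)
  invisible(path)
}
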