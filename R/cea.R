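#' Net monetary benefit
#'
#' `NMB = wtp * delta_qaly - delta_cost`.  A positive value means the
#' comparator is cost-effective versus the reference at the stated
#' willingness-to-pay threshold.
#'
#' @param delta_cost Incremental cost (comparator minus reference), EUR.
#' @param delta_qaly Incremental QALYs (comparator minus reference).
#' @param wtp Willingness-to-pay threshold, EUR/QALY, `>= 0`.
#' @return NMB in EUR.
#' @examples
#' net_monetary_benefit(-8725, 0.008, 40000)  # 9045
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, wtp) {
  if (!is.numeric(wtp) || any(wtp < 0)) stop_param("'wtp' must be >= 0")
  wtp * delta_qaly - delta_cost
}

#' Classify the incremental result into a dominance quadrant
#'
#' A comparator that saves costs without losing QALYs is *dominant*
#' (the ICER is meaningless); one that costs more while losing QALYs is
#' *dominated*.  In the remaining quadrants the ICER
#' `delta_cost / delta_qaly` is reported; when `delta_qaly` is exactly 0
#' there, the ICER is returned as `NA` rather than raising a division
#' error.
#'
#' @inheritParams net_monetary_benefit
#' @return A list with `label` (one of `"dominant"`, `"dominated"`,
#'   `"icer_defined"`) and `icer` (number or `NA`).
#' @examples
#' classify_dominance(-8725, 0.008)
#' @export
classify_dominance <- function(delta_cost, delta_qaly) {
  if (delta_cost < 0 && delta_qaly >= 0) {
    list(label = "dominant", icer = NA_real_)
  } else if (delta_cost > 0 && delta_qaly <= 0) {
    list(label = "dominated", icer = NA_real_)
  } else {
    icer <- if (delta_qaly == 0) NA_real_ else delta_cost / delta_qaly
    list(label = "icer_defined", icer = icer)
  }
}

#' Incremental cost-effectiveness analysis of two arms
#'
#' Computes incremental discounted costs and QALYs (comparator minus
#' reference), the dominance classification or ICER, and the net
#' monetary benefit at the given threshold.  By the convention of the
#' base case, cryoablation (PCA) is the comparator and robotic partial
#' nephrectomy (RAPN) the reference, so cost savings appear as negative
#' incremental cost.
#'
#' @param reference,comparator `arm_outcome` objects from
#'   [run_strategy()], computed under the same shared parameters.
#' @param wtp Willingness-to-pay threshold; defaults to the one carried
#'   by the outcomes.
#' @return A `cea_result` list.
#' @examples
#' sh <- shared_params()
#' res <- incremental_analysis(
#'   run_strategy(strategy_params("RAPN", 15293, 0.025, 1.90), sh),
#'   run_strategy(strategy_params("PCA", 7427, 0.055, 1.13), sh))
#' res$nmb
#' @export
incremental_analysis <- function(reference, comparator, wtp = NULL) {
  stopifnot(inherits(reference, "arm_outcome"), inherits(comparator, "arm_outcome"))
  if (reference$horizon_cycles != comparator$horizon_cycles)
    stop_param("arms were run over different horizons (%d vs %d cycles)",
               reference$horizon_cycles, comparator$horizon_cycles)
  if (reference$discount_annual != comparator$discount_annual)
    stop_param("arms were run under different discount rates")
  wtp <- wtp %||% reference$wtp
  delta_cost <- comparator$cost_discounted - reference$cost_discounted
  delta_qaly <- comparator$qaly_discounted - reference$qaly_discounted
  dom <- classify_dominance(delta_cost, delta_qaly)
  structure(list(
    reference = reference$strategy, comparator = comparator$strategy,
    cost_a = reference$cost_discounted, qaly_a = reference$qaly_discounted,
    cost_b = comparator$cost_discounted, qaly_b = comparator$qaly_discounted,
    delta_cost = delta_cost, delta_qaly = delta_qaly,
    label = dom$label, icer = dom$icer,
    nmb = net_monetary_benefit(delta_cost, delta_qaly, wtp),
    wtp = wtp
  ), class = "cea_result")
}

#' Base-case results as a table
#'
#' Lays a `cea_result` out as the familiar two-row CEA table: absolute
#' cost and QALYs per arm, incremental columns, ICER/dominance and NMB on
#' the comparator row.
#'
#' @param result A `cea_result` from [incremental_analysis()].
#' @param digits_qaly Decimals for QALY presentation (default 3).
#' @return A data frame with one row per arm.
#' @export
cea_table <- function(result, digits_qaly = 3) {
  stopifnot(inherits(result, "cea_result"))
  icer_txt <- switch(result$label,
    dominant = "Dominant",
    dominated = "Dominated",
    icer_defined = if (is.na(result$icer)) "Undefined"
                   else sprintf("%.0f", result$icer))
  data.frame(
    arm = c(result$reference, result$comparator),
    cost = round(c(result$cost_a, result$cost_b), 2),
    qalys = round(c(result$qaly_a, result$qaly_b), digits_qaly),
    delta_cost = c(NA, round(result$delta_cost, 2)),
    delta_qalys = c(NA, round(result$delta_qaly, digits_qaly)),
    icer = c(NA, icer_txt),
    nmb = c(NA, round(result$nmb, 2))
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Incremental analysis: %s vs %s (WTP %s EUR/QALY)\n",
              x$comparator, x$reference, format(x$wtp, big.mark = ",")))
  print(cea_table(x), row.names = FALSE)
  invisible(x)
}
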