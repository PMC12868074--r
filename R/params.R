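#' Health states of the cohort model
#'
#' The model tracks a treated cohort through four mutually exclusive
#' states: stable disease, local recurrence, metastatic disease and death
#' (absorbing).  The order of this vector fixes the row/column order of
#' every transition matrix and trace.
#'
#' @format Character vector of length 4.
#' @export
markov_states <- c("stable", "local_recurrence", "metastatic", "dead")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_param("'%s' must be a single probability in [0, 1], got %s",
               name, format(x))
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_param("'%s' must be a single non-negative number", name)
  invisible(x)
}

#' Metastatic survival specification
#'
#' Survival in the metastatic state is governed by a parameterised
#' survival curve.  The default family is exponential (a constant monthly
#' death probability, memoryless, so no tunnel states are needed); a
#' Weibull family is available and is applied through a time-in-model
#' approximation, i.e. the conditional monthly death probability at cycle
#' `t` is `1 - S(t + 1)/S(t)` with `S(t) = exp(-(t/scale)^shape)`.
#'
#' @param family `"exponential"` or `"weibull"`.
#' @param p_month Monthly death probability (exponential family).
#' @param shape,scale Weibull shape and scale (scale in months).
#' @return An object of class `met_survival_spec`.
#' @examples
#' met_survival_spec("exponential", p_month = 0.0376)
#' @export
met_survival_spec <- function(family = c("exponential", "weibull"),
                              p_month = NULL, shape = NULL, scale = NULL) {
  family <- match.arg(family)
  if (family == "exponential") {
    if (is.null(p_month)) stop_param("exponential family requires 'p_month'")
    check_prob(p_month, "p_month")
    spec <- list(family = "exponential", p_month = p_month)
  } else {
    if (is.null(shape) || is.null(scale))
      stop_param("weibull family requires 'shape' and 'scale'")
    check_nonneg(shape, "shape"); check_nonneg(scale, "scale")
    if (shape <= 0 || scale <= 0)
      stop_param("weibull 'shape' and 'scale' must be positive")
    spec <- list(family = "weibull", shape = shape, scale = scale)
  }
  structure(spec, class = "met_survival_spec")
}

#' Conditional monthly death probability in the metastatic state
#'
#' @param spec A [met_survival_spec()].
#' @param cycle Cycle index (months since model entry), `>= 0`.
#' @return Probability of metastatic death during the cycle.
#' @export
p_met_month <- function(spec, cycle = 0) {
  stopifnot(inherits(spec, "met_survival_spec"))
  if (any(cycle < 0)) stop_param("'cycle' must be >= 0")
  if (spec$family == "exponential") {
    rep_len(spec$p_month, length(cycle))
  } else {
    S <- function(t) exp(-(t / spec$scale)^spec$shape)
    1 - S(cycle + 1) / S(cycle)
  }
}

#' Strategy-independent model parameters
#'
#' All strategy-independent inputs of the cost-utility model: monthly
#' transition probabilities, the metastatic survival curve, annual
#' utilities, the one-off intervention-month QALY and complication
#' disutility, costs, discounting, horizon and the willingness-to-pay
#' threshold.  Defaults are the base case of the analysis; see the
#' packaged `basecase_table1.yaml` and the methods vignette.
#'
#' @param p_local_recurrence Monthly probability of local recurrence from
#'   stable disease.
#' @param p_metastasis Monthly probability of metastatic progression
#'   (from stable disease and from local recurrence).
#' @param p_background_death Monthly all-cause (background) mortality.
#' @param met_mortality A [met_survival_spec()] for excess mortality in
#'   the metastatic state.
#' @param u_stable,u_local_recurrence,u_metastatic Annual utilities of
#'   the three alive states, each in `[0, 1]`; monthly accrual is
#'   `utility / 12`.
#' @param q_intervention_month QALY accrued during the procedure month
#'   (cycle 0) irrespective of state.
#' @param du_complication One-time QALY decrement per severe
#'   (Clavien-Dindo III+) complication, applied in cycle 0 in expectation
#'   (`p_complication * du_complication`).
#' @param c_complication One-time cost per severe complication (EUR).
#' @param c_advanced_monthly Monthly cost of the metastatic (advanced
#'   disease) state (EUR).
#' @param c_local_recurrence_monthly Monthly cost of the local-recurrence
#'   state (EUR); 0 by default ("advanced disease" costing is read as
#'   metastatic only).
#' @param c_bed_night Cost per hospital bed night (EUR), multiplied by a
#'   strategy's mean length of stay in cycle 0.  The constructor default
#'   is 0; the packaged base case carries a tariff derived in the methods
#'   vignette.
#' @param discount_annual Annual discount rate applied to both costs and
#'   QALYs; the cycle-`m` factor is `(1 + discount_annual)^(-m/12)`.
#' @param horizon_cycles Model horizon in monthly cycles.
#' @param wtp Willingness-to-pay threshold (EUR/QALY).
#' @param half_cycle_correction Logical; if `TRUE`, state accrual in
#'   cycles `>= 1` uses the mid-cycle average of the bounding occupancies.
#' @return An object of class `shared_params` (a validated list).
#' @examples
#' sp <- shared_params()
#' sp$p_metastasis
#' @export
shared_params <- function(p_local_recurrence = 0.0018,
                          p_metastasis = 0.0035,
                          p_background_death = 0.0012,
                          met_mortality = met_survival_spec("exponential",
                                                           p_month = 1 - 0.10^(1 / 60)),
                          u_stable = 0.76,
                          u_local_recurrence = 0.70,
                          u_metastatic = 0.66,
                          q_intervention_month = 0.058,
                          du_complication = 0.05,
                          c_complication = 4332,
                          c_advanced_monthly = 2500,
                          c_local_recurrence_monthly = 0,
                          c_bed_night = 0,
                          discount_annual = 0.03,
                          horizon_cycles = 60,
                          wtp = 40000,
                          half_cycle_correction = FALSE) {
  if (!inherits(met_mortality, "met_survival_spec"))
    stop_param("'met_mortality' must be a met_survival_spec object")
  for (nm in c("p_local_recurrence", "p_metastasis", "p_background_death",
               "u_stable", "u_local_recurrence", "u_metastatic",
               "q_intervention_month", "du_complication"))
    check_prob(get(nm), nm)
  if (p_local_recurrence + p_metastasis + p_background_death >= 1)
    stop_param("monthly transition probabilities out of stable disease sum to >= 1")
  for (nm in c("c_complication", "c_advanced_monthly",
               "c_local_recurrence_monthly", "c_bed_night", "discount_annual"))
    check_nonneg(get(nm), nm)
  if (!is.numeric(horizon_cycles) || horizon_cycles < 1 ||
      horizon_cycles != round(horizon_cycles))
    stop_param("'horizon_cycles' must be a positive integer")
  check_nonneg(wtp, "wtp")
  structure(list(
    p_local_recurrence = p_local_recurrence,
    p_metastasis = p_metastasis,
    p_background_death = p_background_death,
    met_mortality = met_mortality,
    u_stable = u_stable,
    u_local_recurrence = u_local_recurrence,
    u_metastatic = u_metastatic,
    q_intervention_month = q_intervention_month,
    du_complication = du_complication,
    c_complication = c_complication,
    c_advanced_monthly = c_advanced_monthly,
    c_local_recurrence_monthly = c_local_recurrence_monthly,
    c_bed_night = c_bed_night,
    discount_annual = discount_annual,
    horizon_cycles = as.integer(horizon_cycles),
    wtp = wtp,
    half_cycle_correction = isTRUE(half_cycle_correction)
  ), class = "shared_params")
}

#' Strategy-specific parameters
#'
#' @param name Strategy label, e.g. `"PCA"` or `"RAPN"`.
#' @param c_procedure One-time procedure cost (EUR).
#' @param p_complication Probability of a severe (Clavien-Dindo III+)
#'   complication within 90 days.
#' @param mean_los Mean length of stay in nights (used for reporting and,
#'   when `c_bed_night > 0`, for cycle-0 bed costing).
#' @param p_local_recurrence,p_metastasis Optional strategy-specific
#'   overrides of the shared monthly event probabilities (used by the
#'   one-way sensitivity analysis, which varies them per arm); `NULL`
#'   means "use the shared value".
#' @return An object of class `strategy_params`.
#' @examples
#' strategy_params("PCA", c_procedure = 7427, p_complication = 0.055,
#'                 mean_los = 1.13)
#' @export
strategy_params <- function(name, c_procedure, p_complication, mean_los = 0,
                            p_local_recurrence = NULL, p_metastasis = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_nonneg(c_procedure, "c_procedure")
  check_prob(p_complication, "p_complication")
  check_nonneg(mean_los, "mean_los")
  if (!is.null(p_local_recurrence)) check_prob(p_local_recurrence, "p_local_recurrence")
  if (!is.null(p_metastasis)) check_prob(p_metastasis, "p_metastasis")
  structure(list(name = name,
                 c_procedure = c_procedure,
                 p_complication = p_complication,
                 mean_los = mean_los,
                 p_local_recurrence = p_local_recurrence,
                 p_metastasis = p_metastasis),
            class = "strategy_params")
}

#' @export
print.shared_params <- function(x, ...) {
  cat("Shared model parameters (monthly cycle,", x$horizon_cycles, "cycles)\n")
  cat(sprintf("  transitions/month: LR %.4f, met %.4f, death %.4f\n",
              x$p_local_recurrence, x$p_metastasis, x$p_background_death))
  cat(sprintf("  metastatic mortality: %s\n",
              if (x$met_mortality$family == "exponential")
                sprintf("exponential, p = %.4f/month", x$met_mortality$p_month)
              else sprintf("weibull(shape %.3g, scale %.3g mo)",
                           x$met_mortality$shape, x$met_mortality$scale)))
  cat(sprintf("  utilities/yr: stable %.2f, LR %.2f, met %.2f; intervention month %.3f\n",
              x$u_stable, x$u_local_recurrence, x$u_metastatic,
              x$q_intervention_month))
  cat(sprintf("  discount %.1f%%/yr, WTP %s EUR/QALY\n",
              100 * x$discount_annual, format(x$wtp, big.mark = ",")))
  invisible(x)
}

#' @export
print.strategy_params <- function(x, ...) {
  cat(sprintf("Strategy %s: procedure %s EUR, complications %.1f%%, LOS %.2f nights\n",
              x$name, format(x$c_procedure, big.mark = ","),
              100 * x$p_complication, x$mean_los))
  invisible(x)
}
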