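#' Bundle a two-strategy model for analysis
#'
#' Holds the shared parameters and the two strategies so the incremental
#' result and the sensitivity analysis can rerun the full model.
#'
#' @param shared A [shared_params()].
#' @param reference,comparator [strategy_params()] objects (reference is
#'   the baseline arm the deltas subtract).
#' @param wtp Willingness-to-pay override; defaults to `shared$wtp`.
#' @return A `cea_model` list.
#' @examples
#' m <- cea_model(shared_params(),
#'                strategy_params("RAPN", 15293, 0.025, 1.90),
#'                strategy_params("PCA", 7427, 0.055, 1.13))
#' base_nmb(m)
#' @export
cea_model <- function(shared, reference, comparator, wtp = NULL) {
  stopifnot(inherits(shared, "shared_params"),
            inherits(reference, "strategy_params"),
            inherits(comparator, "strategy_params"))
  structure(list(shared = shared, reference = reference,
                 comparator = comparator, wtp = wtp %||% shared$wtp),
            class = "cea_model")
}

#' Run a `cea_model` and return its incremental result
#'
#' @param model A [cea_model()].
#' @return A `cea_result`.
#' @export
run_cea <- function(model) {
  stopifnot(inherits(model, "cea_model"))
  incremental_analysis(run_strategy(model$reference, model$shared),
                       run_strategy(model$comparator, model$shared),
                       wtp = model$wtp)
}

#' @rdname run_cea
#' @return `base_nmb()`: the net monetary benefit of the model as given.
#' @export
base_nmb <- function(model) run_cea(model)$nmb

# Registry of addressable scalar parameters.  `where` is "shared" or the
# arm slot; `domain` drives clamping under +/-20% variation.  Event
# probabilities are exposed per arm (the sweep varies them one arm at a
# time even though base values are shared).
param_registry <- function(model) {
  shared_ids <- data.frame(
    id = c("p_background_death", "p_met_month",
           "u_stable", "u_local_recurrence", "u_metastatic",
           "q_intervention_month", "du_complication",
           "c_complication", "c_advanced_monthly",
           "c_local_recurrence_monthly", "c_bed_night",
           "discount_annual"),
    where = "shared",
    field = c("p_background_death", "p_met_month",
              "u_stable", "u_local_recurrence", "u_metastatic",
              "q_intervention_month", "du_complication",
              "c_complication", "c_advanced_monthly",
              "c_local_recurrence_monthly", "c_bed_night",
              "discount_annual"),
    domain = c("prob", "prob", "prob", "prob", "prob", "prob", "prob",
               "cost", "cost", "cost", "cost", "cost")
  )
  arm_ids <- do.call(rbind, lapply(c("reference", "comparator"), function(slot) {
    nm <- model[[slot]]$name
    data.frame(
      id = paste0(c("c_procedure_", "p_complication_", "mean_los_",
                    "p_local_recurrence_", "p_metastasis_"), nm),
      where = slot,
      field = c("c_procedure", "p_complication", "mean_los",
                "p_local_recurrence", "p_metastasis"),
      domain = c("cost", "prob", "cost", "prob", "prob")
    )
  }))
  rbind(shared_ids, arm_ids)
}

param_get <- function(model, row) {
  if (row$where == "shared") {
    if (row$field == "p_met_month") {
      if (model$shared$met_mortality$family != "exponential")
        stop_param("'p_met_month' is only addressable for exponential metastatic mortality")
      model$shared$met_mortality$p_month
    } else model$shared[[row$field]]
  } else {
    model[[row$where]][[row$field]] %||% model$shared[[row$field]]
  }
}

param_set <- function(model, row, value) {
  if (row$where == "shared") {
    if (row$field == "p_met_month")
      model$shared$met_mortality <- met_survival_spec("exponential", p_month = value)
    else model$shared[[row$field]] <- value
  } else {
    model[[row$where]][[row$field]] <- value
  }
  model
}

#' Parameters swept by the deterministic sensitivity analysis
#'
#' The default sweep covers the 17 scalar model inputs: the three shared
#' transition probabilities (background mortality shared; local
#' recurrence and metastasis exposed per arm), metastatic mortality, the
#' five utility/disutility inputs and the three shared costs, plus
#' procedure cost and complication probability per arm.  Willingness to
#' pay, the discount convention and the horizon are not part of the
#' swept set; `mean_los`, `c_bed_night`, `c_local_recurrence_monthly`
#' and `discount_annual` are addressable by [one_way()] but excluded
#' from the default tornado.
#'
#' @param model A [cea_model()].
#' @return Character vector of parameter ids.
#' @export
dsa_parameters <- function(model) {
  stopifnot(inherits(model, "cea_model"))
  reg <- param_registry(model)
  excluded <- c("discount_annual", "c_bed_night", "c_local_recurrence_monthly",
                paste0("mean_los_", c(model$reference$name, model$comparator$name)))
  setdiff(reg$id, excluded)
}

#' One-way deterministic sensitivity analysis of a single parameter
#'
#' Sets the parameter to `(1 - rel_range)` and `(1 + rel_range)` times
#' its base value (clamped to its valid domain, with a warning when
#' clamping bites), reruns the full model at each value, and reports the
#' two NMBs and their absolute difference (the tornado swing).  The model
#' object is never mutated; the base value is untouched.
#'
#' @param model A [cea_model()].
#' @param param_id One id from the registry (see [dsa_parameters()];
#'   `mean_los_<arm>`, `c_bed_night`, `c_local_recurrence_monthly` and
#'   `discount_annual` are also accepted).
#' @param rel_range Relative variation, default 0.2 (i.e. +/-20%).
#' @return A one-row data frame (`tornado_entry`).
#' @examples
#' m <- cea_model(shared_params(),
#'                strategy_params("RAPN", 15293, 0.025, 1.90),
#'                strategy_params("PCA", 7427, 0.055, 1.13))
#' one_way(m, "c_procedure_RAPN")
#' @export
one_way <- function(model, param_id, rel_range = 0.2) {
  stopifnot(inherits(model, "cea_model"))
  reg <- param_registry(model)
  row <- reg[reg$id == param_id, ]
  if (nrow(row) != 1L)
    stop_param("unknown parameter '%s'; valid ids: %s",
               param_id, paste(reg$id, collapse = ", "))
  base <- param_get(model, row)
  lo <- (1 - rel_range) * base
  hi <- (1 + rel_range) * base
  if (row$domain == "prob") {
    clamped_hi <- min(hi, 1)
    if (clamped_hi < hi)
      warning(sprintf("'%s' high value %.4g clamped to 1", param_id, hi))
    hi <- clamped_hi
    lo <- max(lo, 0)
  }
  nmb_low <- base_nmb(param_set(model, row, lo))
  nmb_high <- base_nmb(param_set(model, row, hi))
  data.frame(param_id = param_id, base_value = base,
             low_value = lo, high_value = hi,
             nmb_low = nmb_low, nmb_high = nmb_high,
             swing = abs(nmb_high - nmb_low))
}

#' Tornado analysis
#'
#' Runs [one_way()] over a set of parameters and orders the entries by
#' decreasing swing (ties broken lexicographically by id), truncated to
#' the `top_k` most influential.
#'
#' @param model A [cea_model()].
#' @param top_k Number of entries to keep (default 17).
#' @param rel_range Relative variation per parameter (default 0.2).
#' @param params Ids to sweep; defaults to [dsa_parameters()].
#' @return A `tornado` data frame ordered by swing.
#' @export
tornado <- function(model, top_k = 17, rel_range = 0.2,
                    params = dsa_parameters(model)) {
  stopifnot(inherits(model, "cea_model"), length(params) >= 1)
  entries <- do.call(rbind, lapply(params, one_way,
                                   model = model, rel_range = rel_range))
  ord <- order(-entries$swing, entries$param_id)
  out <- utils::head(entries[ord, , drop = FALSE], top_k)
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}
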