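shared_fields <- c("p_local_recurrence", "p_metastasis", "p_background_death",
                   "met_mortality", "u_stable", "u_local_recurrence",
                   "u_metastatic", "q_intervention_month", "du_complication",
                   "c_complication", "c_advanced_monthly",
                   "c_local_recurrence_monthly", "c_bed_night",
                   "discount_annual", "horizon_cycles", "wtp",
                   "half_cycle_correction")
strategy_fields <- c("name", "c_procedure", "p_complication", "mean_los",
                     "p_local_recurrence", "p_metastasis")
required_shared <- setdiff(shared_fields,
                           c("c_local_recurrence_monthly", "c_bed_night",
                             "half_cycle_correction"))
required_strategy <- c("name", "c_procedure", "p_complication", "mean_los")

cohort_columns <- c("id", "arm", "age", "sex", "cci", "asa", "bmi", "egfr",
                    "tumor_size", "renal_score", "ecog", "time_lr", "event_lr",
                    "time_met", "event_met", "complication", "los")

check_keys <- function(x, required, allowed, what) {
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop_param("%s: missing required keys: %s", what,
               paste(missing, collapse = ", "))
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop_param("%s: unknown keys: %s", what, paste(unknown, collapse = ", "))
  invisible(x)
}

#' Load model parameters from YAML
#'
#' Reads a parameter document with a `shared` block (the fields of
#' [shared_params()]; `met_mortality` is a nested block with `family`
#' and its parameters) and a `strategies` list (fields of
#' [strategy_params()]).  Missing required keys, unknown keys and
#' out-of-domain values each raise a distinct error naming the key.
#' The packaged base case is
#' `system.file("extdata", "basecase_table1.yaml", package = "renalcea")`.
#'
#' @param path Path to the YAML file.
#' @return List with `shared` ([shared_params()]) and `strategies`
#'   (named list of [strategy_params()]).
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop_param("parameter file '%s' does not exist", path)
  doc <- yaml::read_yaml(path)
  check_keys(doc, c("shared", "strategies"), c("shared", "strategies"),
             "parameter file")
  check_keys(doc$shared, required_shared, shared_fields, "shared block")
  ms <- doc$shared$met_mortality
  check_keys(ms, "family",
             c("family", "p_month", "shape", "scale"), "met_mortality block")
  doc$shared$met_mortality <- do.call(met_survival_spec, ms)
  shared <- do.call(shared_params, doc$shared)
  strategies <- lapply(doc$strategies, function(s) {
    check_keys(s, required_strategy, strategy_fields,
               sprintf("strategy block '%s'", s$name %||% "?"))
    do.call(strategy_params, s)
  })
  names(strategies) <- vapply(strategies, `[[`, character(1), "name")
  list(shared = shared, strategies = strategies)
}

#' Write model parameters to YAML
#'
#' Inverse of [load_parameters()]: writing then reading reproduces the
#' parameter objects exactly (up to YAML number formatting).
#'
#' @param shared A [shared_params()].
#' @param strategies List of [strategy_params()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(shared, strategies, path) {
  stopifnot(inherits(shared, "shared_params"))
  sh <- unclass(shared)
  sh$met_mortality <- unclass(sh$met_mortality)
  strat <- lapply(strategies, function(s) Filter(Negate(is.null), unclass(s)))
  yaml::write_yaml(list(shared = sh, strategies = unname(strat)), path,
                   precision = 12)
  invisible(path)
}

#' Read / write a patient-level cohort CSV
#'
#' The cohort CSV has one row per patient and the columns of the
#' synthetic generator's output (UTF-8, header row, `.` decimal).  A
#' missing column raises a schema error naming it.
#'
#' @param path CSV path.
#' @return `read_cohort()`: the cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_param("cohort file '%s' does not exist", path)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_columns, names(dat))
  if (length(missing))
    stop_param("cohort CSV is missing columns: %s",
               paste(missing, collapse = ", "))
  dat
}

#' @rdname read_cohort
#' @param cohort Cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Load / write a synthetic-cohort scenario from YAML
#'
#' The YAML document carries the arguments of [synthetic_scenario()];
#' the packaged emulation scenario is
#' `system.file("extdata", "scenario_nephspare_like.yaml", package = "renalcea")`
#' (a synthetic emulation of the published covariate imbalance, not
#' patient data).
#'
#' @param path YAML path.
#' @return A [synthetic_scenario()].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop_param("scenario file '%s' does not exist", path)
  doc <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n` key as boolean FALSE; map it back
  names(doc)[names(doc) %in% c("FALSE", "false")] <- "n"
  allowed <- names(formals(synthetic_scenario))
  check_keys(doc, character(0), allowed, "scenario file")
  # YAML maps arrive as named lists; flatten the numeric-vector fields
  if (!is.null(doc$propensity$coef)) doc$propensity$coef <- unlist(doc$propensity$coef)
  if (!is.null(doc$complications)) doc$complications <- unlist(doc$complications)
  if (!is.null(doc$events))
    doc$events <- lapply(doc$events, function(ev) {
      ev$coef <- unlist(ev$coef); ev
    })
  for (p in c("asa_probs", "renal_probs", "ecog_probs"))
    if (!is.null(doc$covariates[[p]])) doc$covariates[[p]] <- unlist(doc$covariates[[p]])
  do.call(synthetic_scenario, doc)
}

#' @rdname load_scenario
#' @param scenario A [synthetic_scenario()].
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  doc <- unclass(scenario)
  doc$complications <- as.list(doc$complications)
  doc$propensity$coef <- as.list(doc$propensity$coef)
  doc$events <- lapply(doc$events, function(ev) {
    ev$coef <- as.list(ev$coef); ev
  })
  for (p in c("asa_probs", "renal_probs", "ecog_probs"))
    doc$covariates[[p]] <- as.list(doc$covariates[[p]])
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' End-to-end run: obtain a cohort (given, or generated from a
#' scenario), fit the propensity model and stabilized weights, tabulate
#' balance, estimate weighted hazard ratios and Kaplan-Meier curves for
#' both endpoints, compare complication proportions and length of stay,
#' run the Markov cost-utility model for both strategies, and sweep the
#' tornado.  Deterministic given `(inputs, seed)`.
#'
#' @param params List from [load_parameters()] (or an equivalent
#'   `list(shared =, strategies =)`).
#' @param cohort Optional patient-level data frame; when `NULL` one is
#'   generated from `scenario`.
#' @param scenario A [synthetic_scenario()] used when `cohort` is `NULL`.
#' @param seed RNG seed for cohort generation.
#' @param reference,comparator Strategy names (defaults `"RAPN"` and
#'   `"PCA"`).
#' @param stabilized Use stabilized weights (default `TRUE`).
#' @param top_k Tornado entries to keep.
#' @param out_dir Optional directory; when given, the report bundle is
#'   written there (CSV tables, JSON results and a plain-text run log).
#' @return A `cea_report` list with elements `cohort_summary`,
#'   `propensity`, `balance`, `cox`, `km`, `complications`, `cea`,
#'   `tornado`, `arms` and `log`.
#' @export
run_pipeline <- function(params, cohort = NULL, scenario = synthetic_scenario(),
                         seed = scenario$seed, reference = "RAPN",
                         comparator = "PCA", stabilized = TRUE, top_k = 17,
                         out_dir = NULL) {
  stopifnot(inherits(params$shared, "shared_params"))
  for (nm in c(reference, comparator))
    if (is.null(params$strategies[[nm]]))
      stop_param("pipeline: no strategy named '%s' in parameters", nm)

  if (is.null(cohort)) cohort <- generate_cohort(scenario, seed = seed)

  fit <- fit_propensity(cohort, treated = comparator)
  w <- stabilized_weights(fit, stabilized = stabilized)
  bal <- balance_table(fit$data, w, treated = comparator)
  cox <- lapply(c(local_recurrence = "local_recurrence",
                  metastasis = "metastasis"),
                function(ep) tryCatch(
                  weighted_cox(fit$data, w, ep, treated = comparator),
                  error = function(e) structure(
                    list(endpoint = ep, error = conditionMessage(e)),
                    class = "cox_result")))
  km <- lapply(c(local_recurrence = "local_recurrence",
                 metastasis = "metastasis"),
               function(ep) weighted_km(fit$data, w, ep))

  comp_counts <- tapply(cohort$complication, cohort$arm, sum)
  arm_n <- table(cohort$arm)
  comp_test <- compare_proportions(comp_counts[[comparator]], arm_n[[comparator]],
                                   comp_counts[[reference]], arm_n[[reference]])

  model <- cea_model(params$shared, params$strategies[[reference]],
                     params$strategies[[comparator]])
  arms <- list(reference = run_strategy(model$reference, model$shared),
               comparator = run_strategy(model$comparator, model$shared))
  cea <- incremental_analysis(arms$reference, arms$comparator, wtp = model$wtp)
  torn <- tornado(model, top_k = top_k)

  cohort_summary <- data.frame(
    arm = names(arm_n), n = as.integer(arm_n),
    complications = as.integer(comp_counts[names(arm_n)]),
    mean_los = as.numeric(tapply(cohort$los, cohort$arm, mean)[names(arm_n)]),
    mean_age = as.numeric(tapply(cohort$age, cohort$arm, mean)[names(arm_n)]),
    mean_tumor_size = as.numeric(tapply(cohort$tumor_size, cohort$arm,
                                        mean)[names(arm_n)]))

  log_lines <- c(
    sprintf("renalcea %s", as.character(utils::packageVersion("renalcea"))),
    sprintf("seed: %s", format(seed)),
    sprintf("cohort: n = %d (%s)", nrow(cohort),
            if (is.null(scenario)) "supplied" else "generated"),
    sprintf("weights: %s", if (stabilized) "stabilized" else "unstabilized"),
    sprintf("strategies: %s (reference) vs %s (comparator)",
            reference, comparator))

  report <- structure(list(
    cohort_summary = cohort_summary, propensity = fit, balance = bal,
    cox = cox, km = km,
    complications = c(comp_test,
                      list(x1 = comp_counts[[comparator]], n1 = arm_n[[comparator]],
                           x2 = comp_counts[[reference]], n2 = arm_n[[reference]])),
    cea = cea, tornado = torn, arms = arms, log = log_lines
  ), class = "cea_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a report bundle to disk
#'
#' @param report A `cea_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "cea_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  utils::write.csv(report$cohort_summary, p("cohort_summary.csv"), row.names = FALSE)
  utils::write.csv(report$balance, p("balance_table.csv"), row.names = FALSE)
  utils::write.csv(cea_table(report$cea), p("cea_table.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$tornado), p("tornado.csv"), row.names = FALSE)
  for (ep in names(report$km))
    utils::write.csv(report$km[[ep]], p(sprintf("km_%s.csv", ep)), row.names = FALSE)
  for (slot in names(report$arms))
    write_trace(report$arms[[slot]], p(sprintf("trace_%s.csv",
                                               report$arms[[slot]]$strategy)))
  cox_out <- lapply(report$cox, function(cr) cr[setdiff(names(cr), "endpoint")])
  jsonlite::write_json(cox_out, p("cox_results.json"), auto_unbox = TRUE,
                       digits = NA)
  writeLines(report$log, p("run_log.txt"))
  invisible(out_dir)
}

#' @export
print.cea_report <- function(x, ...) {
  cat("== Cohort ==\n"); print(x$cohort_summary, row.names = FALSE)
  cat(sprintf("\nComplications (Clavien-Dindo III+): %.1f%% vs %.1f%%; p = %.3f\n",
              100 * x$complications$p1, 100 * x$complications$p2,
              x$complications$p_value))
  cat("\n== Weighted hazard ratios ==\n")
  for (cr in x$cox)
    if (is.null(cr$error)) print(cr) else
      cat(sprintf("%s: %s\n", cr$endpoint, cr$error))
  cat("\n== Cost-effectiveness ==\n"); print(x$cea)
  cat("\n== Tornado (top entries) ==\n")
  print(utils::head(as.data.frame(x$tornado), 5), row.names = FALSE)
  invisible(x)
}
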