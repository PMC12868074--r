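# Shared fixtures: all built in code at test time.

basecase <- function() {
  load_parameters(system.file("extdata", "basecase_table1.yaml",
                              package = "renalcea"))
}

basecase_model <- function() {
  prm <- basecase()
  cea_model(prm$shared, prm$strategies$RAPN, prm$strategies$PCA)
}

# shared parameters with every hazard switched off
null_shared <- function(...) {
  shared_params(p_local_recurrence = 0, p_metastasis = 0,
                p_background_death = 0,
                met_mortality = met_survival_spec("exponential", p_month = 0),
                ...)
}

pca_strategy <- function(...) {
  strategy_params("PCA", c_procedure = 7427, p_complication = 0.055,
                  mean_los = 1.13, ...)
}

rapn_strategy <- function(...) {
  strategy_params("RAPN", c_procedure = 15293, p_complication = 0.025,
                  mean_los = 1.90, ...)
}

# random valid shared parameters for property-style checks
random_shared <- function() {
  repeat {
    p <- stats::runif(3, 0, 0.3)
    if (sum(p) < 1) break
  }
  shared_params(p_local_recurrence = p[1], p_metastasis = p[2],
                p_background_death = p[3],
                met_mortality = met_survival_spec("exponential",
                                                  p_month = stats::runif(1)),
                discount_annual = stats::runif(1, 0, 0.06),
                horizon_cycles = 60)
}

# hand-built trace: whole cohort in one state from cycle 1 on
degenerate_trace <- function(state, horizon) {
  occ <- matrix(0, horizon + 1, 4, dimnames = list(NULL, markov_states))
  occ[1, "stable"] <- 1
  occ[-1, state] <- 1
  out <- data.frame(cycle = 0:horizon, occ)
  class(out) <- c("cohort_trace", "data.frame")
  attr(out, "horizon_cycles") <- horizon
  out
}

# small survival toy with distinct event times for the Cox oracle
cox_toy <- function() {
  data.frame(
    id = 1:8,
    arm = rep(c("PCA", "RAPN"), each = 4),
    time_lr = c(3, 7, 11, 15, 2, 6, 10, 18),
    event_lr = c(1, 1, 0, 1, 1, 0, 1, 1),
    time_met = c(5, 9, 12, 20, 4, 8, 14, 16),
    event_met = c(1, 0, 1, 1, 1, 1, 0, 1)
  )
}

# Breslow log partial likelihood for a single binary covariate
breslow_loglik <- function(beta, time, event, treat, weights = rep(1, length(time))) {
  risk <- exp(beta * treat)
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    ll <- ll + weights[i] * (beta * treat[i] -
                               log(sum(weights[at_risk] * risk[at_risk])))
  }
  ll
}
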