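# Small in-code fixtures shared across test files.

# A fully observed wide feature table for one patient: hours 0..(n_hours-1),
# deterministic values so window contents can be enumerated by hand.
tiny_feature_table <- function(patient_id = "P1", n_hours = 3, vars = c("A", "B")) {
  d <- expand.grid(hour = 0:(n_hours - 1), stringsAsFactors = FALSE)
  out <- data.frame(patient_id = patient_id, hour = d$hour)
  for (j in seq_along(vars)) {
    out[[vars[j]]] <- 100 * j + d$hour   # value encodes (variable, hour)
  }
  out
}

# A small fully preprocessed cohort for model-level tests: quick to window
# and train on.
tiny_cohort_windows <- function(n_event = 10, n_censored = 20, n_vars = 4,
                                horizon_steps = 6, seed = 1,
                                drift_amplitude = 3) {
  spec <- cohort_spec(
    n_event = n_event, n_censored = n_censored, n_vars = n_vars,
    hazard_weights = c(rep(0.4, min(2, n_vars)), rep(0, max(0, n_vars - 2))),
    true_shape = 1.5, baseline_scale = 24, censor_median = 30,
    drift_amplitude = drift_amplitude,
    missing_rate_hourly = 0, missing_rate_daily = 0, daily_var_fraction = 0,
    seed = seed
  )
  cohort <- generate_cohort(spec)
  series <- cohort_series_long(cohort)
  patients <- cohort_patient_table(cohort)
  feats <- suppressMessages(
    select_common_features(series, sprintf("V%02d", seq_len(n_vars)))
  )
  win <- build_windows(feats, patients, horizon_steps = horizon_steps,
                       tau = 72, max_windows = 12)
  list(spec = spec, cohort = cohort, patients = patients, windows = win)
}

# Independent midrank AUC oracle: O(n^2) pairwise comparison.
brute_force_auc <- function(cases, controls) {
  wins <- 0
  for (x in cases) {
    wins <- wins + sum(x > controls) + 0.5 * sum(x == controls)
  }
  wins / (length(cases) * length(controls))
}
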