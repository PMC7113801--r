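#' Specification of a synthetic ICU cohort
#'
#' Collects every knob of the synthetic-data generator. The defaults emulate
#' the structure of a medical-ICU cardiac-arrest cohort: 37 event patients
#' and 722 censored patients, 45 time-dependent clinical variables of which a
#' fraction are sampled daily (laboratory tests) and the rest hourly (vitals,
#' organ-failure scores), substantial missingness, event times following an
#' accelerated-failure-time Weibull model whose log-scale depends on a subset
#' of covariates, and censored stays log-normally distributed around a 72 h
#' median and capped downstream at the safety threshold `tau`.
#'
#' @param n_event Number of patients experiencing the event (cardiac arrest).
#' @param n_censored Number of censored (non-event) patients.
#' @param n_vars Number of time-dependent variables (default 45).
#' @param horizon_steps Window length in hours used downstream (default 48).
#' @param tau Censoring safety threshold in hours (default 72).
#' @param hazard_weights Per-variable coefficients linking each patient's
#'   baseline covariate levels to the log-scale of their event-time
#'   distribution (accelerated-failure-time form). Default: the first 10
#'   variables carry weight 0.25, the rest 0. A scalar is recycled.
#' @param true_shape Weibull shape of simulated event times.
#' @param baseline_scale Weibull scale in hours at the covariate mean.
#' @param censor_median,censor_sdlog Median (hours) and log-SD of the
#'   log-normal censored stay-length distribution; stays are truncated to
#'   at least 2 h.
#' @param drift_onset Hours before the event at which covariate derangement
#'   begins for event patients (default 16).
#' @param drift_amplitude Size of the pre-event covariate ramp at one hour
#'   before arrest, in baseline-SD units (default 3).
#' @param missing_rate_hourly,missing_rate_daily Mean per-cell deletion
#'   probabilities for hourly and daily variables.
#' @param daily_var_fraction Fraction of variables observed only daily.
#' @param rate_dispersion Concentration of the Beta distribution from which
#'   each patient's personal deletion rate is drawn (mean = the configured
#'   rate); heterogeneous data quality is what gives the missingness filters
#'   something to exclude. `Inf` means an identical rate for every patient.
#'   Default 20.
#' @param min_outcome_hours Lower truncation (hours) applied to event times
#'   and censored stays via inverse-CDF sampling; 0 disables truncation.
#'   Setting it to `horizon_steps` yields cohorts in which every patient can
#'   contribute a full set of windows.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return An object of class `cohort_spec` (a validated list).
#' @seealso [generate_cohort()], [inject_missingness()]
#' @export
cohort_spec <- function(n_event = 37L, n_censored = 722L, n_vars = 45L,
                        horizon_steps = 48L, tau = 72,
                        hazard_weights = NULL,
                        true_shape = 1.5, baseline_scale = 60,
                        censor_median = 72, censor_sdlog = 0.6,
                        drift_onset = 16, drift_amplitude = 3,
                        missing_rate_hourly = 0.15, missing_rate_daily = 0.05,
                        daily_var_fraction = 0.4,
                        rate_dispersion = 20,
                        min_outcome_hours = 0,
                        seed = 1L) {
  if (!is.numeric(n_event) || n_event < 1) {
    stop_config("'n_event' must be >= 1")
  }
  if (!is.numeric(n_censored) || n_censored < 0) {
    stop_config("'n_censored' must be >= 0")
  }
  check_positive_scalar(n_vars, "n_vars")
  check_positive_scalar(horizon_steps, "horizon_steps")
  check_positive_scalar(tau, "tau")
  check_positive_scalar(true_shape, "true_shape")
  check_positive_scalar(baseline_scale, "baseline_scale")
  check_positive_scalar(censor_median, "censor_median")
  check_rate(missing_rate_hourly, "missing_rate_hourly")
  check_rate(missing_rate_daily, "missing_rate_daily")
  check_rate(daily_var_fraction, "daily_var_fraction")
  if (!is.numeric(min_outcome_hours) || min_outcome_hours < 0) {
    stop_config("'min_outcome_hours' must be >= 0")
  }
  n_vars <- as.integer(n_vars)
  if (is.null(hazard_weights)) {
    hazard_weights <- numeric(n_vars)
    hazard_weights[seq_len(min(10L, n_vars))] <- 0.25
  }
  hazard_weights <- rep_len(as.numeric(hazard_weights), n_vars)
  spec <- structure(list(
    n_event = as.integer(n_event), n_censored = as.integer(n_censored),
    n_vars = n_vars, horizon_steps = as.integer(horizon_steps), tau = tau,
    hazard_weights = hazard_weights, true_shape = true_shape,
    baseline_scale = baseline_scale, censor_median = censor_median,
    censor_sdlog = censor_sdlog, drift_onset = drift_onset,
    drift_amplitude = drift_amplitude,
    missing_rate_hourly = missing_rate_hourly,
    missing_rate_daily = missing_rate_daily,
    daily_var_fraction = daily_var_fraction,
    rate_dispersion = rate_dispersion,
    min_outcome_hours = min_outcome_hours,
    seed = as.integer(seed)
  ), class = "cohort_spec")
  spec
}

# Variable names; the trailing block of size round(daily_var_fraction * n_vars)
# plays the role of daily-sampled laboratory tests.
cohort_var_names <- function(spec) {
  sprintf("V%02d", seq_len(spec$n_vars))
}

#' @rdname cohort_spec
#' @param spec A `cohort_spec`.
#' @export
daily_variables <- function(spec) {
  n_daily <- round(spec$daily_var_fraction * spec$n_vars)
  v <- cohort_var_names(spec)
  if (n_daily == 0) character(0) else utils::tail(v, n_daily)
}

# Truncated inverse-CDF draws: X | X >= lo for a distribution with
# quantile function qfun and cdf pfun.
rtrunc <- function(n, pfun, qfun, lo) {
  p0 <- if (lo > 0) pfun(lo) else 0
  qfun(stats::runif(n, p0, 1))
}

#' Generate a seeded synthetic ICU cohort
#'
#' Produces `n_event + n_censored` patient records. Each patient carries a
#' per-variable baseline level (standard normal across patients); the hourly
#' trajectory of a variable is baseline + AR(1) noise. Event times follow a
#' Weibull accelerated-failure-time model: shape `true_shape`, and log-scale
#' \eqn{\log \lambda_i = \log(\text{baseline\_scale}) - w^\top b_i} where
#' \eqn{b_i} are the patient's baseline levels and \eqn{w} the hazard
#' weights, so deranged covariates shorten the time to arrest. In the final
#' `drift_onset` hours before their event, event patients' hazard-linked
#' variables additionally ramp linearly towards deranged values
#' (`drift_amplitude` baseline-SD units at one hour before arrest), making
#' short-horizon risk learnable from recent history. Censored stays are
#' log-normal (median `censor_median`, truncated to >= 2 h) and independent
#' of the event mechanism.
#'
#' Trajectories are fully observed here; apply [inject_missingness()] for the
#' mixed hourly/daily sampling and missing-data structure of real ICU data.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `icu_cohort`: a list of patient records, each
#'   with fields `patient_id`, `series` (hours x variables matrix, hour 0 in
#'   row 1), `static` (demographics), `event` (1 = cardiac arrest observed,
#'   0 = censored) and `outcome_time` (hours, continuous). The spec is
#'   attached as attribute `"spec"`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop_config("'spec' must be created by cohort_spec()")
  }
  with_seed(spec$seed, {
    n <- spec$n_event + spec$n_censored
    ids <- sprintf("P%04d", seq_len(n))
    event <- rep(c(1L, 0L), c(spec$n_event, spec$n_censored))
    vars <- cohort_var_names(spec)

    records <- vector("list", n)
    for (i in seq_len(n)) {
      baseline <- stats::rnorm(spec$n_vars)
      if (event[i] == 1L) {
        lam_i <- spec$baseline_scale *
          exp(-sum(spec$hazard_weights * baseline))
        # arrests charted within the first hour are unusable downstream
        lo <- max(spec$min_outcome_hours, 1.05)
        outcome <- rtrunc(1,
          function(q) stats::pweibull(q, spec$true_shape, lam_i),
          function(p) stats::qweibull(p, spec$true_shape, lam_i),
          lo)
      } else {
        lo <- max(2, spec$min_outcome_hours)
        outcome <- rtrunc(1,
          function(q) stats::plnorm(q, log(spec$censor_median), spec$censor_sdlog),
          function(p) stats::qlnorm(p, log(spec$censor_median), spec$censor_sdlog),
          lo)
      }
      n_hours <- ceiling(outcome)
      # AR(1) noise around the patient's baseline level
      phi <- 0.8
      innov_sd <- 0.6
      noise <- matrix(stats::rnorm(n_hours * spec$n_vars, sd = innov_sd),
                      n_hours, spec$n_vars)
      if (n_hours > 1) {
        for (h in 2:n_hours) noise[h, ] <- phi * noise[h - 1, ] + noise[h, ]
      }
      series <- sweep(noise, 2, baseline, "+")
      if (event[i] == 1L && spec$drift_amplitude > 0) {
        hrs <- seq_len(n_hours) - 1
        ramp <- pmax(0, 1 - (outcome - hrs) / spec$drift_onset)
        drifted <- which(spec$hazard_weights != 0)
        if (length(drifted)) {
          series[, drifted] <- series[, drifted] +
            outer(ramp, spec$drift_amplitude * sign(spec$hazard_weights[drifted]))
        }
      }
      colnames(series) <- vars
      rownames(series) <- as.character(seq_len(n_hours) - 1)
      static <- list(
        age = round(stats::rnorm(1, 65, 12), 1),
        sex = sample(c("F", "M"), 1),
        weight = round(stats::rnorm(1, 65, 15), 1),
        dx_cardiac = stats::rbinom(1, 1, 0.3),
        dx_renal = stats::rbinom(1, 1, 0.2),
        dx_diabetes = stats::rbinom(1, 1, 0.25)
      )
      records[[i]] <- list(
        patient_id = ids[i], series = series, static = static,
        event = event[i], outcome_time = outcome
      )
    }
    structure(records, spec = spec, class = "icu_cohort")
  })
}

#' @export
print.icu_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  ev <- vapply(x, `[[`, integer(1), "event")
  cat("Synthetic ICU cohort:", length(x), "patients (",
      sum(ev == 1L), "event /", sum(ev == 0L), "censored ),",
      spec$n_vars, "variables\n")
  ot <- vapply(x, `[[`, numeric(1), "outcome_time")
  cat("Outcome times (h): median", round(stats::median(ot), 1),
      " range", round(min(ot), 1), "-", round(max(ot), 1), "\n")
  invisible(x)
}

#' Impose the hourly/daily sampling scheme and random missingness
#'
#' Daily variables (the trailing `daily_var_fraction` block, see
#' [daily_variables()]) retain values only every 24th hour. Remaining cells
#' are independently deleted: hourly variables at a per-patient rate drawn
#' from a Beta distribution with mean `missing_rate_hourly` and concentration
#' `rate_dispersion` (heterogeneous data quality across patients; `Inf` for a
#' common rate), daily variables at `missing_rate_daily`. For every event
#' patient, at least one variable is guaranteed observed at the final
#' pre-outcome hour, so the "observed at least one hour before arrest"
#' inclusion rule remains satisfiable.
#'
#' @param cohort An `icu_cohort` from [generate_cohort()].
#' @param spec The cohort's [cohort_spec()]; defaults to the one attached to
#'   `cohort`.
#' @return The cohort with `NA`s injected into the series matrices.
#' @export
inject_missingness <- function(cohort, spec = attr(cohort, "spec")) {
  if (!inherits(cohort, "icu_cohort")) {
    stop_config("'cohort' must be an icu_cohort")
  }
  check_rate(spec$missing_rate_hourly, "missing_rate_hourly")
  check_rate(spec$missing_rate_daily, "missing_rate_daily")
  daily <- daily_variables(spec)
  with_seed(stage_seed(spec$seed, 104729L), {
    out <- lapply(cohort, function(rec) {
      s <- rec$series
      hrs <- as.integer(rownames(s))
      is_daily <- colnames(s) %in% daily
      if (any(is_daily)) {
        s[hrs %% 24L != 0L, is_daily] <- NA_real_
      }
      p_hr <- spec$missing_rate_hourly
      p_dy <- spec$missing_rate_daily
      if (is.finite(spec$rate_dispersion) && p_hr > 0 && p_hr < 1) {
        p_hr <- stats::rbeta(1, spec$rate_dispersion * spec$missing_rate_hourly,
                             spec$rate_dispersion * (1 - spec$missing_rate_hourly))
      }
      if (any(!is_daily) && p_hr > 0) {
        blk <- s[, !is_daily, drop = FALSE]
        del <- matrix(stats::runif(length(blk)) < p_hr, nrow(blk), ncol(blk))
        blk[del] <- NA_real_
        s[, !is_daily] <- blk
      }
      if (any(is_daily) && p_dy > 0) {
        drows <- hrs %% 24L == 0L
        blk <- s[drows, is_daily, drop = FALSE]
        del <- matrix(stats::runif(length(blk)) < p_dy, nrow(blk), ncol(blk))
        blk[del] <- NA_real_
        s[drows, is_daily] <- blk
      }
      if (rec$event == 1L) {
        # protect one observation at the final eligible prediction hour
        t_final <- floor(rec$outcome_time - 1)
        row <- which(hrs == t_final)
        if (length(row) == 1L && all(is.na(s[row, ]))) {
          s[row, 1L] <- rec$series[row, 1L]
        }
      }
      rec$series <- s
      rec
    })
    attributes(out) <- attributes(cohort)
    out
  })
}

#' Write / read a cohort as delimited text
#'
#' `write_cohort()` writes `series.csv` (patient_id, hour, variable, value;
#' one row per observed cell) and `patients.csv` (patient_id, event,
#' outcome_time, static covariates) into `dir`. `read_cohort_series()` and
#' `read_cohort_patients()` read them back as data frames.
#'
#' @param cohort An `icu_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()`: the two file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series <- cohort_series_long(cohort)
  patients <- cohort_patient_table(cohort)
  sp <- file.path(dir, "series.csv")
  pp <- file.path(dir, "patients.csv")
  utils::write.csv(series, sp, row.names = FALSE, quote = FALSE)
  utils::write.csv(patients, pp, row.names = FALSE, quote = FALSE)
  invisible(c(series = sp, patients = pp))
}

#' @rdname write_cohort
#' @export
cohort_series_long <- function(cohort) {
  do.call(rbind, lapply(cohort, function(rec) {
    obs <- which(!is.na(rec$series), arr.ind = TRUE)
    if (nrow(obs) == 0L) return(NULL)
    data.frame(
      patient_id = rec$patient_id,
      hour = as.integer(rownames(rec$series))[obs[, 1L]],
      variable = colnames(rec$series)[obs[, 2L]],
      value = rec$series[obs],
      stringsAsFactors = FALSE
    )
  }))
}

#' @rdname write_cohort
#' @export
cohort_patient_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(rec) {
    data.frame(patient_id = rec$patient_id, event = rec$event,
               outcome_time = rec$outcome_time,
               as.data.frame(rec$static, stringsAsFactors = FALSE),
               stringsAsFactors = FALSE)
  }))
}

#' @rdname write_cohort
#' @param path Path to a `series.csv` / `patients.csv` file.
#' @export
read_cohort_series <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_cohort
#' @export
read_cohort_patients <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
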