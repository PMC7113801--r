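#' Pivot long-format clinical series to a common-feature table
#'
#' Restricts a long-format series (`patient_id`, `hour`, `variable`, `value`)
#' to the required common variables and pivots it to one row per
#' (patient, hour) with one column per variable. Patients for whom a required
#' variable is never observed are flagged (attribute `"flagged_patients"` and
#' a message), not dropped: downstream missingness filters decide exclusion.
#'
#' @param series Long-format data frame with columns `patient_id`, `hour`,
#'   `variable`, `value`.
#' @param required_vars Character vector of variable names to keep.
#' @return Wide data frame `patient_id`, `hour`, then one numeric column per
#'   required variable (`NA` where unobserved), ordered by patient and hour.
#' @export
select_common_features <- function(series, required_vars) {
  if (length(required_vars) == 0L) {
    stop_config("'required_vars' must name at least one variable")
  }
  need <- c("patient_id", "hour", "variable", "value")
  if (!all(need %in% names(series))) {
    stop_data("series must have columns: ", paste(need, collapse = ", "))
  }
  keep <- series[series$variable %in% required_vars, , drop = FALSE]
  wide <- stats::reshape(
    keep, idvar = c("patient_id", "hour"), timevar = "variable",
    direction = "wide", v.names = "value"
  )
  names(wide) <- sub("^value\\.", "", names(wide))
  for (v in setdiff(required_vars, names(wide))) wide[[v]] <- NA_real_
  wide <- wide[, c("patient_id", "hour", required_vars), drop = FALSE]
  wide <- wide[order(wide$patient_id, wide$hour), , drop = FALSE]
  rownames(wide) <- NULL
  observed <- vapply(split(wide[required_vars], wide$patient_id),
                     function(d) colSums(!is.na(d)) > 0,
                     logical(length(required_vars)))
  flagged <- colnames(observed)[!apply(observed, 2, all)]
  if (length(flagged)) {
    message(length(flagged),
            " patient(s) missing at least one required variable entirely: ",
            paste(utils::head(flagged, 5), collapse = ", "),
            if (length(flagged) > 5) ", ..." else "")
  }
  attr(wide, "flagged_patients") <- flagged
  wide
}

#' Per-patient missing-observation statistics
#'
#' For each patient, `p_id` counts the missing cells of their
#' (hour x variable) grid and `p_ir = p_id / total cells` is the missing
#' ratio; both drive the exclusion filters of [filter_patients()]. Variables
#' listed in `daily_vars` are sampled once per day, so their cells are
#' counted on the daily grid (hours divisible by 24) rather than the hourly
#' one; with `daily_vars = NULL` the denominator is exactly
#' hours x variables.
#'
#' @param feature_table Wide table from [select_common_features()].
#' @param daily_vars Optional character vector of daily-sampled variables.
#' @param patients Optional vector of patient ids that must be present; a
#'   listed patient with no observation rows is an error naming the patient.
#' @return Data frame `patient_id`, `p_id`, `p_ir`, `n_cells`.
#' @export
compute_missingness <- function(feature_table, daily_vars = NULL,
                                patients = NULL) {
  vars <- setdiff(names(feature_table), c("patient_id", "hour"))
  if (!is.null(patients)) {
    absent <- setdiff(patients, unique(feature_table$patient_id))
    if (length(absent)) {
      stop_data("patient(s) with zero observation rows: ",
                paste(absent, collapse = ", "))
    }
  }
  hourly <- setdiff(vars, daily_vars)
  daily <- intersect(vars, daily_vars)
  out <- lapply(split(feature_table, feature_table$patient_id), function(d) {
    miss <- sum(is.na(d[hourly]))
    cells <- nrow(d) * length(hourly)
    if (length(daily)) {
      drows <- d$hour %% 24L == 0L
      miss <- miss + sum(is.na(d[drows, daily]))
      cells <- cells + sum(drows) * length(daily)
    }
    data.frame(patient_id = d$patient_id[1L], p_id = miss,
               p_ir = if (cells > 0) miss / cells else 0,
               n_cells = cells, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exclude patients with excessive missingness
#'
#' Retains exactly the patients with `p_id <= p_id_max` and
#' `p_ir <= p_ir_max` (defaults: 1000 missing observations and a 20 %
#' missing ratio). One message per exclusion names the violated criterion.
#'
#' @param stats Data frame from [compute_missingness()].
#' @param p_id_max Maximum allowed missing-observation count.
#' @param p_ir_max Maximum allowed missing ratio.
#' @param quiet Suppress per-exclusion messages.
#' @return Character vector of retained patient ids (possibly empty, with a
#'   warning).
#' @export
filter_patients <- function(stats, p_id_max = 1000, p_ir_max = 0.2,
                            quiet = FALSE) {
  bad_id <- stats$p_id > p_id_max
  bad_ir <- stats$p_ir > p_ir_max
  keep <- !(bad_id | bad_ir)
  if (!quiet) {
    for (i in which(!keep)) {
      why <- c(
        if (bad_id[i]) sprintf("p_id = %d > %g", stats$p_id[i], p_id_max),
        if (bad_ir[i]) sprintf("p_ir = %.3f > %g", stats$p_ir[i], p_ir_max)
      )
      message("excluding ", stats$patient_id[i], ": ",
              paste(why, collapse = "; "))
    }
  }
  if (!any(keep)) warning("all patients excluded by missingness filters")
  stats$patient_id[keep]
}

#' Cap censored remaining times at the safety threshold
#'
#' Censored observations only bound the true event time from below; leaving
#' very long censored remaining times in the likelihood biases the model
#' towards predicting safety. Remaining times of censored observations are
#' therefore capped at `tau` (72 h by default, the median ICU stay); event
#' observations are untouched.
#'
#' @param remaining_time Hours remaining, > 0. Vectorised.
#' @param u Event indicator (1 = event, 0 = censored), recycled.
#' @param tau Cap in hours, > 0.
#' @return Capped remaining times.
#' @examples
#' cap_censored_tte(100, u = 0, tau = 72)  # 72
#' cap_censored_tte(100, u = 1, tau = 72)  # 100, events untouched
#' @export
cap_censored_tte <- function(remaining_time, u, tau = 72) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop_config("'tau' must be a single positive number")
  }
  u <- rep_len(u, length(remaining_time))
  ifelse(u == 0, pmin(remaining_time, tau), remaining_time)
}

#' Build the masked 3-D window tensor with time-to-event labels
#'
#' Implements the sliding-window construction: for each retained patient and
#' each eligible prediction hour `t`, one observation holds the most recent
#' `min(t + 1, horizon_steps)` hourly covariate vectors, right-aligned so the
#' last step is hour `t` itself, left-padded with masked steps. Eligible
#' hours are integers with at least one hour remaining to the event
#' (`outcome_time - t >= 1`) for event patients, or before the censoring time
#' for censored patients; each patient contributes at most `max_windows`
#' (default `horizon_steps`) eligible hours. Event patients keep their
#' *latest* eligible hours (anchored at the event, so the near-event windows
#' the inclusion rule emphasises are always present and every whole number
#' of remaining hours up to `max_windows` is covered); censored patients
#' keep their *earliest* hours (anchored at admission, where remaining time
#' to censoring is large — the situation the safety cap `tau` exists for).
#' Labels carry `remaining_time = outcome_time - t`, capped at `tau` for
#' censored observations via [cap_censored_tte()].
#'
#' Within a window, present values are carried forward (last observation
#' carried forward, never across the window's left edge or across patients);
#' a step is masked only when its entire variable vector is unobserved.
#'
#' @param feature_table Wide table from [select_common_features()], already
#'   restricted to retained patients or not (patients are taken from
#'   `patients`).
#' @param patients Data frame with columns `patient_id`, `event`,
#'   `outcome_time` for the patients to window.
#' @param horizon_steps Window length in hours (steps).
#' @param tau Censoring cap in hours.
#' @param max_windows Maximum windows per patient.
#' @param max_windows_censored Maximum windows per censored patient
#'   (default `max_windows`); censored stays contribute the bulk of the
#'   observations, so capping them separately scales compute without
#'   touching event-window coverage.
#' @return An object of class `labeled_window_set`: list with `values`
#'   (array observations x steps x variables), `mask` (observations x steps
#'   logical, `TRUE` = step is all-missing and skipped), `labels` (data frame
#'   `obs_id`, `patient_id`, `prediction_hour`, `remaining_time`, `u`),
#'   `vars`, `horizon_steps`, `tau`, and `standardized` flag.
#' @export
build_windows <- function(feature_table, patients, horizon_steps = 48L,
                          tau = 72, max_windows = horizon_steps,
                          max_windows_censored = max_windows) {
  if (horizon_steps < 1) stop_config("'horizon_steps' must be >= 1")
  check_positive_scalar(tau, "tau")
  vars <- setdiff(names(feature_table), c("patient_id", "hour"))
  n_vars <- length(vars)
  horizon_steps <- as.integer(horizon_steps)

  tab_by_pat <- split(feature_table, feature_table$patient_id)
  per_patient <- vector("list", nrow(patients))
  dropped <- character(0)
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    ev <- patients$event[i]
    otime <- patients$outcome_time[i]
    t_max <- if (ev == 1) floor(otime - 1) else ceiling(otime) - 1
    if (t_max < 0) {
      dropped <- c(dropped, pid)
      next
    }
    if (ev == 1) {
      t_min <- max(0, t_max - as.integer(max_windows) + 1L)
      hours_t <- t_min:t_max
    } else {
      hours_t <- 0:min(t_max, as.integer(max_windows_censored) - 1L)
    }

    d <- tab_by_pat[[pid]]
    h_top <- max(hours_t)
    M <- matrix(NA_real_, h_top + 1L, n_vars, dimnames = list(NULL, vars))
    if (!is.null(d)) {
      rows <- d$hour <= h_top
      M[d$hour[rows] + 1L, ] <- as.matrix(d[rows, vars, drop = FALSE])
    }
    # index of the most recent observed hour per (hour, variable); 0 = none
    L <- apply(ifelse(is.na(M), 0L, row(M)), 2, cummax)
    if (is.null(dim(L))) L <- matrix(L, nrow = nrow(M))
    step_all_missing <- rowSums(!is.na(M)) == 0L

    wins <- vector("list", length(hours_t))
    for (j in seq_along(hours_t)) {
      t <- hours_t[j]
      lo <- t - horizon_steps + 1L        # first hour in the window
      rows <- max(lo, 0L):t + 1L          # rows of M inside the stay
      n_pad <- horizon_steps - length(rows)
      Li <- L[rows, , drop = FALSE]
      Li[Li < max(lo, 0L) + 1L] <- 0L     # no carry across the window edge
      vals <- M[cbind(pmax(as.vector(Li), 1L), as.vector(col(Li)))]
      vals[Li == 0L] <- NA_real_
      vals <- matrix(vals, length(rows), n_vars)
      msk <- step_all_missing[rows]
      if (n_pad > 0) {
        vals <- rbind(matrix(NA_real_, n_pad, n_vars), vals)
        msk <- c(rep(TRUE, n_pad), msk)
      }
      wins[[j]] <- list(vals = vals, msk = msk)
    }
    remaining <- otime - hours_t
    per_patient[[i]] <- list(
      pid = pid, u = ev, hours = hours_t,
      remaining = cap_censored_tte(remaining, ev, tau),
      wins = wins
    )
  }
  if (length(dropped)) {
    warning("excluded ", length(dropped),
            " event patient(s) with event before hour 1: ",
            paste(dropped, collapse = ", "))
  }
  per_patient <- Filter(Negate(is.null), per_patient)
  n_obs <- sum(vapply(per_patient, function(p) length(p$hours), integer(1)))

  values <- array(NA_real_, c(n_obs, horizon_steps, n_vars),
                  dimnames = list(NULL, NULL, vars))
  mask <- matrix(TRUE, n_obs, horizon_steps)
  labels <- vector("list", length(per_patient))
  o <- 0L
  for (i in seq_along(per_patient)) {
    p <- per_patient[[i]]
    for (j in seq_along(p$wins)) {
      o <- o + 1L
      values[o, , ] <- p$wins[[j]]$vals
      mask[o, ] <- p$wins[[j]]$msk
    }
    labels[[i]] <- data.frame(
      patient_id = p$pid, prediction_hour = p$hours,
      remaining_time = p$remaining, u = p$u, stringsAsFactors = FALSE
    )
  }
  labels <- do.call(rbind, labels)
  labels <- cbind(obs_id = seq_len(n_obs), labels)
  rownames(labels) <- NULL
  structure(list(
    values = values, mask = mask, labels = labels, vars = vars,
    horizon_steps = horizon_steps, tau = tau, standardized = FALSE,
    scaler = NULL
  ), class = "labeled_window_set")
}

#' @export
print.labeled_window_set <- function(x, ...) {
  d <- dim(x$values)
  cat("Labeled window set:", d[1], "observations x", d[2], "steps x",
      d[3], "variables\n")
  cat("  event observations:", sum(x$labels$u == 1),
      " censored:", sum(x$labels$u == 0), "\n")
  cat("  masked steps:", sum(x$mask), sprintf("(%.1f%%)", 100 * mean(x$mask)),
      " standardized:", x$standardized, "\n")
  invisible(x)
}

#' Subset a window set by observation
#'
#' @param x A `labeled_window_set`.
#' @param obs Integer or logical index into observations.
#' @return A `labeled_window_set` holding the selected observations.
#' @export
subset_windows <- function(x, obs) {
  stopifnot(inherits(x, "labeled_window_set"))
  out <- x
  out$values <- x$values[obs, , , drop = FALSE]
  out$mask <- x$mask[obs, , drop = FALSE]
  out$labels <- x$labels[obs, , drop = FALSE]
  out$labels$obs_id <- seq_len(nrow(out$labels))
  rownames(out$labels) <- NULL
  out
}

#' Training-fold standardization of a window set
#'
#' `fit_scaler()` computes per-variable means and standard deviations over
#' the unmasked, observed cells of (what should be) training-fold
#' observations only, so no validation information leaks into the transform.
#' `standardize_windows()` applies a fitted scaler: observed cells are
#' z-scored, cells still missing after within-window carry-forward are set to
#' 0 (the training mean), and masked steps are zero-filled (the network skips
#' them). `invert_scaler()` undoes the z-scoring on a values array, so
#' inverse(forward(x)) recovers observed cells exactly.
#'
#' @param windows A `labeled_window_set`.
#' @param scaler A scaler from [fit_scaler()].
#' @return `fit_scaler()`: object of class `wtte_scaler` (fields `mean`,
#'   `sd` per variable). `standardize_windows()`: the standardized window
#'   set with the scaler attached. `invert_scaler()`: a values array on the
#'   original scale.
#' @export
fit_scaler <- function(windows) {
  stopifnot(inherits(windows, "labeled_window_set"))
  v <- windows$values
  d <- dim(v)
  unmasked <- !windows$mask                     # obs x steps
  m <- numeric(d[3]); s <- numeric(d[3])
  for (j in seq_len(d[3])) {
    cells <- v[, , j][unmasked]
    cells <- cells[!is.na(cells)]
    m[j] <- if (length(cells)) mean(cells) else 0
    s[j] <- if (length(cells) > 1) stats::sd(cells) else 0
  }
  zero_var <- s == 0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance variable(s) scaled by 1")
    s[zero_var] <- 1
  }
  structure(list(mean = m, sd = s, vars = windows$vars),
            class = "wtte_scaler")
}

#' @rdname fit_scaler
#' @export
standardize_windows <- function(windows, scaler = NULL) {
  stopifnot(inherits(windows, "labeled_window_set"))
  if (windows$standardized) {
    stop_data("window set is already standardized")
  }
  if (is.null(scaler)) scaler <- fit_scaler(windows)
  v <- windows$values
  d <- dim(v)
  for (j in seq_len(d[3])) {
    v[, , j] <- (v[, , j] - scaler$mean[j]) / scaler$sd[j]
  }
  v[is.na(v)] <- 0
  for (n in seq_len(d[2])) {
    masked_n <- windows$mask[, n]
    if (any(masked_n)) v[masked_n, n, ] <- 0
  }
  windows$values <- v
  windows$standardized <- TRUE
  windows$scaler <- scaler
  windows
}

#' @rdname fit_scaler
#' @param values A values array (observations x steps x variables) on the
#'   standardized scale.
#' @export
invert_scaler <- function(values, scaler) {
  stopifnot(inherits(scaler, "wtte_scaler"))
  d <- dim(values)
  for (j in seq_len(d[3])) {
    values[, , j] <- values[, , j] * scaler$sd[j] + scaler$mean[j]
  }
  values
}
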