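#' Event risk within a horizon
#'
#' The risk score passed to the horizon-indexed ROC analysis: the
#' probability, under an observation's predicted Weibull distribution, that
#' the event occurs within the next `h` hours — the CDF at `h`. It is
#' non-decreasing in `h` and lies in `[0, 1]`.
#'
#' @param shape,scale Predicted Weibull parameters (vectorised).
#' @param h Horizon in hours, > 0.
#' @return Risk probabilities in `[0, 1]`.
#' @export
risk_at_horizon <- function(shape, scale, h) {
  if (!is.numeric(h) || any(h <= 0)) stop_domain("'h' must be > 0")
  weib_cdf(h, shape, scale)
}

#' Case/control score sets per prediction horizon
#'
#' For each horizon `h` of the evaluation grid, cases are event-group
#' observations with `h` hours remaining to the event
#' (`floor(remaining_time) == h`), and controls are censored-group
#' observations: under the default risk-set convention, those whose capped
#' remaining time is at least `h`; under exact matching, those at exactly
#' `h`. Both sides are scored by [risk_at_horizon()] at `h` (or, as an
#' alternative reading, by the predicted density at `h`).
#'
#' @param predictions Pooled out-of-fold predictions from [run_cv()] (or
#'   [predict.wtte_gru()] output): needs `remaining_time`, `u`, `shape`,
#'   `scale`.
#' @param horizons Evaluation horizons in hours (default
#'   `c(1, 8, 16, 24, 32, 40, 48)`).
#' @param control_matching `"risk_set"` (default) or `"exact"`.
#' @param score `"cdf"` (risk within `h`; default) or `"pdf"` (density at
#'   `h`).
#' @return List of `horizon_score_set` objects (fields `horizon`, `cases`,
#'   `controls`, `computable`).
#' @export
horizon_score_sets <- function(predictions,
                               horizons = c(1, 8, 16, 24, 32, 40, 48),
                               control_matching = c("risk_set", "exact"),
                               score = c("cdf", "pdf")) {
  control_matching <- match.arg(control_matching)
  score <- match.arg(score)
  need <- c("remaining_time", "u", "shape", "scale")
  if (!all(need %in% names(predictions))) {
    stop_data("predictions must have columns: ", paste(need, collapse = ", "))
  }
  lapply(horizons, function(h) {
    sc <- if (score == "cdf") {
      risk_at_horizon(predictions$shape, predictions$scale, h)
    } else {
      weib_pdf(h, predictions$shape, predictions$scale)
    }
    is_case <- predictions$u == 1 & floor(predictions$remaining_time) == h
    is_ctrl <- if (control_matching == "risk_set") {
      predictions$u == 0 & predictions$remaining_time >= h
    } else {
      predictions$u == 0 & floor(predictions$remaining_time) == h
    }
    set <- list(horizon = h, cases = sc[is_case], controls = sc[is_ctrl],
                computable = any(is_case) && any(is_ctrl))
    if (!set$computable) {
      warning("horizon ", h, " h: empty case or control set; AUC not computable")
    }
    structure(set, class = "horizon_score_set")
  })
}

#' ROC area and Youden operating point for one score set
#'
#' The AUC is the Mann-Whitney probability that a randomly chosen case
#' outscores a randomly chosen control, ties counted one half (midranks).
#' The operating point maximises Youden's J = sensitivity + specificity - 1
#' over thresholds of the form "positive if score >= t".
#'
#' @param set A `horizon_score_set` from [horizon_score_sets()].
#' @return One-row data frame: `horizon`, `auc`, `sensitivity`,
#'   `specificity`, `threshold`, `n_cases`, `n_controls`. All-`NA` metrics
#'   when the set is not computable.
#' @export
roc_auc <- function(set) {
  stopifnot(inherits(set, "horizon_score_set"))
  n1 <- length(set$cases); n0 <- length(set$controls)
  if (!set$computable) {
    return(data.frame(horizon = set$horizon, auc = NA_real_,
                      sensitivity = NA_real_, specificity = NA_real_,
                      threshold = NA_real_, n_cases = n1, n_controls = n0))
  }
  r <- rank(c(set$cases, set$controls))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(c(set$cases, set$controls)))
  sens <- vapply(thr, function(t) mean(set$cases >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(set$controls < t), numeric(1))
  j <- sens + spec - 1
  best <- which.max(j)
  data.frame(horizon = set$horizon, auc = auc, sensitivity = sens[best],
             specificity = spec[best], threshold = thr[best],
             n_cases = n1, n_controls = n0)
}

#' Horizon-indexed (time-dependent) AUC table
#'
#' Applies [horizon_score_sets()] and [roc_auc()] across the horizon grid,
#' yielding the time-dependent AUC profile with operating-point sensitivity
#' and specificity at each horizon.
#'
#' @inheritParams horizon_score_sets
#' @return Data frame with one row per horizon.
#' @export
tauc_table <- function(predictions, horizons = c(1, 8, 16, 24, 32, 40, 48),
                       control_matching = c("risk_set", "exact"),
                       score = c("cdf", "pdf")) {
  sets <- horizon_score_sets(predictions, horizons,
                             control_matching = control_matching,
                             score = score)
  out <- do.call(rbind, lapply(sets, roc_auc))
  rownames(out) <- NULL
  out
}

#' Group risk trajectories over remaining time
#'
#' For each whole hour of remaining time (to the event for the event group,
#' to capped censoring for the censored group), summarises the distribution
#' of the risk score — the probability of the event within
#' `horizon_for_risk` hours — as median and interquartile range per group.
#' Plotted over decreasing remaining time this shows when the two groups'
#' risk distributions separate.
#'
#' @inheritParams horizon_score_sets
#' @param horizon_for_risk Horizon (hours) of the risk score (default 24).
#' @param times Remaining-time grid in hours (default `48:1`).
#' @return Data frame `group`, `hours_remaining`, `n`, `q25`, `median`,
#'   `q75`.
#' @export
risk_trajectories <- function(predictions, horizon_for_risk = 24,
                              times = 48:1) {
  sc <- risk_at_horizon(predictions$shape, predictions$scale,
                        horizon_for_risk)
  rt <- floor(predictions$remaining_time)
  out <- lapply(times, function(tt) {
    do.call(rbind, lapply(c(event = 1, censored = 0), function(g) {
      sel <- predictions$u == g & rt == tt
      q <- if (any(sel)) stats::quantile(sc[sel], c(0.25, 0.5, 0.75))
           else rep(NA_real_, 3)
      data.frame(group = if (g == 1) "event" else "censored",
                 hours_remaining = tt, n = sum(sel),
                 q25 = q[[1]], median = q[[2]], q75 = q[[3]])
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-patient predicted CDF curves and remaining-time estimates
#'
#' For each of one patient's prediction hours, evaluates the predicted
#' cumulative distribution over a grid of future hours and reports the
#' predicted remaining time (the distribution median). Each curve starts at
#' 0 and is non-decreasing.
#'
#' @param model A fitted [wtte_gru()].
#' @param windows A `labeled_window_set` containing the patient.
#' @param patient_id The patient to profile.
#' @param future_hours Grid of future hours for the CDF (default `0:96`).
#' @return List with `curves` (long data frame `prediction_hour`,
#'   `future_hour`, `cdf`) and `summary` (per prediction hour: predicted
#'   parameters, `predicted_remaining` median, and the true
#'   `remaining_time`).
#' @export
patient_cdf_curves <- function(model, windows, patient_id,
                               future_hours = 0:96) {
  sel <- windows$labels$patient_id == patient_id
  if (!any(sel)) stop_data("no windows for patient ", patient_id)
  pw <- subset_windows(windows, which(sel))
  pred <- predict(model, pw, type = "median")
  curves <- do.call(rbind, lapply(seq_len(nrow(pred)), function(i) {
    data.frame(prediction_hour = pred$prediction_hour[i],
               future_hour = future_hours,
               cdf = weib_cdf(future_hours, pred$shape[i], pred$scale[i]))
  }))
  list(curves = curves, summary = pred)
}

#' Plot group risk trajectories over remaining time
#'
#' Median risk (solid) with interquartile band (dashed) per group, over
#' decreasing hours of remaining time; the hour at which the two groups'
#' bands separate is the visual early-warning lead time.
#'
#' @param trajectories Data frame from [risk_trajectories()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_trajectories <- function(trajectories, ...) {
  ev <- trajectories[trajectories$group == "event", ]
  ce <- trajectories[trajectories$group == "censored", ]
  xlim <- rev(range(trajectories$hours_remaining))
  graphics::plot(ev$hours_remaining, ev$median, type = "l", lwd = 2,
                 xlim = xlim, ylim = c(0, 1),
                 xlab = "hours remaining", ylab = "risk probability", ...)
  graphics::lines(ev$hours_remaining, ev$q25, lty = 2)
  graphics::lines(ev$hours_remaining, ev$q75, lty = 2)
  graphics::lines(ce$hours_remaining, ce$median, lwd = 2, col = "grey55")
  graphics::lines(ce$hours_remaining, ce$q25, lty = 2, col = "grey55")
  graphics::lines(ce$hours_remaining, ce$q75, lty = 2, col = "grey55")
  graphics::legend("topleft", c("event group", "censored group"),
                   col = c("black", "grey55"), lwd = 2, bty = "n")
  invisible(trajectories)
}

#' Plot a horizon-indexed AUC profile
#'
#' @param tauc Data frame from [tauc_table()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_tauc <- function(tauc, ...) {
  graphics::plot(tauc$horizon, tauc$auc, type = "b", ylim = c(0.4, 1),
                 xlab = "hours remaining to event (horizon)",
                 ylab = "time-dependent AUC", ...)
  graphics::abline(h = 0.5, lty = 3, col = "grey50")
  invisible(tauc)
}
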