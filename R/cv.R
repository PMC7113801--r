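#' Stratified patient-level fold assignment
#'
#' Partitions patients into `n_folds` folds, stratified by event indicator so
#' every fold carries its share of the (rare) event patients; all of a
#' patient's observation windows stay in one fold, so folds never share
#' patients. Within each stratum fold sizes differ by at most one patient.
#'
#' @param patients Data frame with columns `patient_id` and `event`.
#' @param n_folds Number of folds (default 5).
#' @param seed Seed for the within-stratum shuffle.
#' @return Named integer vector: fold index (1..n_folds) per patient id.
#' @export
kfold_split <- function(patients, n_folds = 5L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2) stop_config("'n_folds' must be >= 2")
  for (ev in unique(patients$event)) {
    if (sum(patients$event == ev) < n_folds) {
      stop_data("stratum event=", ev, " has fewer patients (",
                sum(patients$event == ev), ") than folds (", n_folds, ")")
    }
  }
  with_seed(seed, {
    fold <- integer(nrow(patients))
    # the round-robin counter continues across strata so the *total* fold
    # sizes also stay within one patient of each other
    offset <- 0L
    for (ev in sort(unique(patients$event), decreasing = TRUE)) {
      idx <- which(patients$event == ev)
      idx <- sample(idx)
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
      offset <- offset + length(idx)
    }
    names(fold) <- patients$patient_id
    fold
  })
}

#' Cross-validated training and pooled out-of-fold prediction
#'
#' The evaluation protocol: patients are split into stratified folds by
#' [kfold_split()]; for each fold a scaler and a network are fitted on the
#' training patients only (no leakage) and Weibull parameters are predicted
#' for every held-out observation. The union of the per-fold validation
#' predictions — each observation predicted exactly once — is what the
#' horizon-indexed ROC analysis consumes.
#'
#' @param windows A raw (unstandardized) `labeled_window_set` covering all
#'   patients.
#' @param patients Data frame with `patient_id` and `event` for the
#'   windowed patients.
#' @param config A [wtte_config()]; its `n_folds` and `seed` drive the
#'   split.
#' @param train_max_obs Optional cap on the number of training observations
#'   per fold (seeded subsample; all event windows are kept eligible).
#'   `NULL` trains on every window. A compute knob only: validation
#'   predictions always cover every held-out observation.
#' @param verbose Print per-fold progress.
#' @return An object of class `wtte_cv`: list with `fits` (per-fold
#'   `wtte_gru` objects), `predictions` (pooled out-of-fold data frame with
#'   `shape`, `scale`, `fold`), `fold` (the assignment) and `config`.
#' @export
run_cv <- function(windows, patients, config = wtte_config(),
                   train_max_obs = NULL, verbose = FALSE) {
  stopifnot(inherits(windows, "labeled_window_set"))
  if (windows$standardized) {
    stop_data("run_cv needs raw windows; standardization is per-fold")
  }
  patients <- patients[patients$patient_id %in% windows$labels$patient_id, ,
                       drop = FALSE]
  fold <- kfold_split(patients, config$n_folds, config$seed)
  obs_fold <- fold[windows$labels$patient_id]
  fits <- vector("list", config$n_folds)
  preds <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    tr_idx <- which(obs_fold != f)
    va_idx <- which(obs_fold == f)
    if (!is.null(train_max_obs) && length(tr_idx) > train_max_obs) {
      tr_idx <- with_seed(stage_seed(config$seed, 7919L * f),
                          sort(sample(tr_idx, train_max_obs)))
    }
    tr <- subset_windows(windows, tr_idx)
    va <- subset_windows(windows, va_idx)
    if (verbose) {
      message(sprintf("fold %d: %d training / %d validation observations",
                      f, length(tr_idx), length(va_idx)))
    }
    cfg <- config
    cfg$seed <- stage_seed(config$seed, 104243L * f)
    fit <- tryCatch(
      wtte_gru(tr, cfg, val = va),
      error = function(e) {
        stop_data("fold ", f, ": ", conditionMessage(e))
      }
    )
    p <- predict(fit, va)
    p$fold <- f
    fits[[f]] <- fit
    preds[[f]] <- p
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  structure(list(fits = fits, predictions = predictions, fold = fold,
                 config = config), class = "wtte_cv")
}

#' @export
print.wtte_cv <- function(x, ...) {
  cat("Cross-validated recurrent Weibull time-to-event model\n")
  cat("  folds:", x$config$n_folds,
      " pooled out-of-fold observations:", nrow(x$predictions), "\n")
  vc <- vapply(x$fits, function(f) {
    h <- f$history
    if (nrow(h) && any(is.finite(h$val_cost))) min(h$val_cost, na.rm = TRUE)
    else NA_real_
  }, numeric(1))
  cat("  best validation cost per fold:",
      paste(sprintf("%.3f", vc), collapse = ", "), "\n")
  invisible(x)
}
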