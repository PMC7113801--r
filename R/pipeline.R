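#' End-to-end run configuration
#'
#' Bundles the cohort specification, preprocessing thresholds, model
#' configuration and evaluation settings of one reproducible pipeline run.
#' All study constants appear here as named defaults: the missingness
#' thresholds (`p_id_max = 1000`, `p_ir_max = 0.2`), the censoring cap
#' (`tau = 72` h), the window length (`horizon_steps = 48`), and the
#' evaluation horizon grid.
#'
#' @param cohort A [cohort_spec()].
#' @param p_id_max,p_ir_max Missingness exclusion thresholds.
#' @param tau Censoring cap in hours.
#' @param horizon_steps Window length in hours.
#' @param max_windows Windows per patient (default `horizon_steps`).
#' @param max_windows_censored Windows per censored patient (default
#'   `max_windows`).
#' @param model A [wtte_config()].
#' @param horizons Evaluation horizon grid in hours.
#' @param control_matching `"risk_set"` or `"exact"` (see
#'   [horizon_score_sets()]).
#' @param score `"cdf"` or `"pdf"` risk score.
#' @param train_max_obs Per-fold training-observation cap (see [run_cv()]).
#' @param out_dir Output directory.
#' @param seed Global seed fanned out to per-stage seeds by fixed offsets.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       p_id_max = 1000, p_ir_max = 0.2,
                       tau = 72, horizon_steps = 48L,
                       max_windows = horizon_steps,
                       max_windows_censored = max_windows,
                       model = wtte_config(),
                       horizons = c(1, 8, 16, 24, 32, 40, 48),
                       control_matching = "risk_set", score = "cdf",
                       train_max_obs = NULL,
                       out_dir = tempfile("wtte_run_"), seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(model, "wtte_config"))
  check_positive_scalar(tau, "tau")
  structure(list(
    cohort = cohort, p_id_max = p_id_max, p_ir_max = p_ir_max, tau = tau,
    horizon_steps = as.integer(horizon_steps),
    max_windows = as.integer(max_windows),
    max_windows_censored = as.integer(max_windows_censored), model = model,
    horizons = horizons, control_matching = control_matching, score = score,
    train_max_obs = train_max_obs, out_dir = out_dir,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys `cohort`, `model` and the remaining [run_config()]
#' arguments; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(lst, fn) {
    if (is.null(lst)) return(fn())
    bad <- setdiff(names(lst), names(formals(fn)))
    if (length(bad)) {
      stop_config("unknown config key(s): ", paste(bad, collapse = ", "))
    }
    do.call(fn, lst)
  }
  cohort <- take(y$cohort, cohort_spec)
  model <- take(y$model, wtte_config)
  rest <- y[setdiff(names(y), c("cohort", "model"))]
  bad <- setdiff(names(rest), names(formals(run_config)))
  if (length(bad)) {
    stop_config("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(run_config, c(list(cohort = cohort, model = model), rest))
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full simulate -> preprocess -> cross-validate -> evaluate pipeline
#'
#' Executes every stage in order, writes all intermediate and final
#' artifacts under `config$out_dir` (`series.csv`, `patients.csv`,
#' `labels.csv`, per-fold training histories, `tauc.csv`,
#' `trajectories.csv`) and a `manifest.json` echoing the configuration,
#' per-stage seeds, row counts and content digests of every output file.
#' Same configuration and seed give identical manifest digests on one
#' machine.
#'
#' @param config A [run_config()].
#' @return The manifest (list), invisibly; its `tauc` element holds the
#'   horizon-AUC table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  log_stage("simulate", "generating cohort (seed ", config$cohort$seed, ")")
  cohort <- generate_cohort(config$cohort)
  cohort <- inject_missingness(cohort)
  paths <- write_cohort(cohort, config$out_dir)
  files <- c(files, paths)
  patients <- cohort_patient_table(cohort)
  series <- cohort_series_long(cohort)
  log_stage("simulate", nrow(patients), " patients, ",
            nrow(series), " observed cells")

  log_stage("preprocess", "selecting common features")
  vars <- cohort_var_names(config$cohort)
  features <- select_common_features(series, vars)
  mstats <- compute_missingness(features,
                                daily_vars = daily_variables(config$cohort))
  keep <- suppressWarnings(
    filter_patients(mstats, config$p_id_max, config$p_ir_max, quiet = TRUE)
  )
  log_stage("preprocess", length(keep), " of ", nrow(patients),
            " patients retained by missingness filters")
  if (length(keep) == 0L) {
    warning("empty cohort after missingness filtering; pipeline stopped")
    manifest <- list(config = unclass(config), retained_patients = 0)
    manifest_path <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, force = TRUE)
    return(invisible(manifest))
  }
  kept_patients <- patients[patients$patient_id %in% keep, , drop = FALSE]
  windows <- build_windows(features, kept_patients,
                           horizon_steps = config$horizon_steps,
                           tau = config$tau,
                           max_windows = config$max_windows,
                           max_windows_censored = config$max_windows_censored)
  lab_path <- file.path(config$out_dir, "labels.csv")
  utils::write.csv(windows$labels, lab_path, row.names = FALSE)
  files <- c(files, lab_path)
  log_stage("preprocess", nrow(windows$labels), " observation windows (",
            sum(windows$labels$u == 1), " event)")

  log_stage("cv", config$model$n_folds, "-fold cross-validation")
  win_path <- file.path(config$out_dir, "windows.rds")
  saveRDS(windows, win_path)
  files <- c(files, win_path)
  cv <- run_cv(windows, kept_patients, config$model,
               train_max_obs = config$train_max_obs)
  for (f in seq_along(cv$fits)) {
    hp <- file.path(config$out_dir, sprintf("history_fold%d.csv", f))
    utils::write.csv(cv$fits[[f]]$history, hp, row.names = FALSE)
    mp <- write_wtte_model(cv$fits[[f]],
                           file.path(config$out_dir,
                                     sprintf("model_fold%d", f)))
    files <- c(files, hp, mp)
  }

  log_stage("evaluate", "horizon-indexed ROC analysis")
  tauc <- tauc_table(cv$predictions, config$horizons,
                     control_matching = config$control_matching,
                     score = config$score)
  tauc_path <- file.path(config$out_dir, "tauc.csv")
  utils::write.csv(tauc, tauc_path, row.names = FALSE)
  traj <- risk_trajectories(cv$predictions)
  traj_path <- file.path(config$out_dir, "trajectories.csv")
  utils::write.csv(traj, traj_path, row.names = FALSE)
  pred_path <- file.path(config$out_dir, "predictions.csv")
  utils::write.csv(cv$predictions, pred_path, row.names = FALSE)
  files <- c(files, tauc_path, traj_path, pred_path)
  if (capabilities("png")) {
    tauc_png <- file.path(config$out_dir, "tauc.png")
    grDevices::png(tauc_png, width = 720, height = 480)
    plot_tauc(tauc, main = "Time-dependent AUC")
    grDevices::dev.off()
    traj_png <- file.path(config$out_dir, "trajectories.png")
    grDevices::png(traj_png, width = 720, height = 480)
    plot_trajectories(traj, main = "Group risk over remaining time")
    grDevices::dev.off()
    files <- c(files, tauc_png, traj_png)
  }

  digests <- as.list(tools::md5sum(unname(files)))
  names(digests) <- basename(names(digests))
  manifest <- list(
    seed = config$seed,
    n_patients = nrow(patients),
    retained_patients = length(keep),
    n_observations = nrow(windows$labels),
    n_event_observations = sum(windows$labels$u == 1),
    tauc = tauc,
    files = digests
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE, digits = NA)
  log_stage("done", "artifacts in ", config$out_dir)
  invisible(manifest)
}
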