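#' Save and restore fitted models
#'
#' `write_wtte_model()` writes the fitted model as an RDS file
#' (`<prefix>.rds`) plus a portable JSON sidecar (`<prefix>.json`) carrying
#' the architecture, the training configuration, the standardization
#' statistics and the training summary, so a fit can be audited or rebuilt
#' outside R. `read_wtte_model()` restores the RDS.
#'
#' @param fit A fitted [wtte_gru()].
#' @param prefix Path prefix (without extension).
#' @return `write_wtte_model()`: the two paths, invisibly;
#'   `read_wtte_model()`: the restored `wtte_gru` object.
#' @export
write_wtte_model <- function(fit, prefix) {
  stopifnot(inherits(fit, "wtte_gru"))
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  rds <- paste0(prefix, ".rds")
  js <- paste0(prefix, ".json")
  saveRDS(fit, rds)
  sidecar <- list(
    architecture = list(
      n_vars = fit$n_vars, horizon_steps = fit$horizon_steps,
      gru_units = fit$config$gru_units,
      dense_units = fit$config$dense_units,
      n_parameters = count_parameters(fit$config, fit$n_vars),
      links = list(shape = "softplus", scale = "exp")
    ),
    config = unclass(fit$config),
    standardization = list(vars = fit$scaler$vars,
                           mean = fit$scaler$mean, sd = fit$scaler$sd),
    training = list(
      epochs_run = nrow(fit$history),
      best_epoch = fit$best_epoch,
      final_train_cost = if (nrow(fit$history)) {
        utils::tail(fit$history$train_cost, 1)
      } else NULL
    )
  )
  jsonlite::write_json(sidecar, js, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(model = rds, sidecar = js))
}

#' @rdname write_wtte_model
#' @param path Path to a `.rds` written by `write_wtte_model()`.
#' @export
read_wtte_model <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "wtte_gru"))
  fit
}
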