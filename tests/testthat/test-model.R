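# The recurrent network, its training engine and cross-validation.

test_that("parameter count follows the architecture arithmetic", {
  cfg <- wtte_config()
  # 3 gates x (45 inputs + 50 recurrent + bias) x 50 units, then dense + heads
  expect_equal(count_parameters(cfg, 45),
               3 * (45 + 50 + 1) * 50 + (50 + 1) * 20 + (20 + 1) * 2)
  expect_equal(count_parameters(cfg, 45), 15462)
  # the initialised weight tensors carry exactly that many scalars
  w <- wtteicu:::init_weights(45, cfg)
  expect_equal(sum(vapply(w, length, integer(1))),
               count_parameters(cfg, 45))
})

test_that("the BPTT gradient matches finite differences through the engine", {
  set.seed(12)
  V <- 3; N <- 4; O <- 6
  cfg <- wtte_config(gru_units = 5, dense_units = 3, seed = 9)
  w <- wtteicu:::init_weights(V, cfg)
  X <- array(rnorm(V * N * O), c(V, N, O))
  valid <- matrix(1, N, O); valid[1:2, 1] <- 0; valid[1, 2] <- 0
  tl <- runif(O, 1, 30); ul <- rbinom(O, 1, 0.5)
  g <- wtteicu:::gru_grad_cpp(X, valid, tl, ul, w)
  num_grad <- function(nm, i) {
    eps <- 1e-6
    wp <- w; wm <- w
    wp[[nm]][i] <- wp[[nm]][i] + eps
    wm[[nm]][i] <- wm[[nm]][i] - eps
    (wtteicu:::gru_cost_cpp(X, valid, tl, ul, wp, 64L) -
       wtteicu:::gru_cost_cpp(X, valid, tl, ul, wm, 64L)) / (2 * eps)
  }
  worst <- 0
  for (nm in names(w)) {
    for (i in sample(length(w[[nm]]), min(4, length(w[[nm]])))) {
      a <- g$grads[[nm]][i]
      n <- num_grad(nm, i)
      worst <- max(worst, abs(a - n) / max(1e-8, abs(a), abs(n)))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("masked padding steps cannot influence predictions", {
  fx <- tiny_cohort_windows(seed = 2)
  ws <- standardize_windows(fx$windows)
  cfg <- wtte_config(gru_units = 6, dense_units = 4, epochs = 3,
                     batch_size = 64, seed = 3)
  fit <- wtte_gru(ws, cfg)
  p0 <- predict(fit, ws)

  # scribbling over masked steps' values changes nothing
  ws_scrib <- ws
  for (o in seq_len(nrow(ws$labels))) {
    m <- ws$mask[o, ]
    if (any(m)) ws_scrib$values[o, m, ] <- 99
  }
  p1 <- predict(fit, ws_scrib)
  expect_equal(p1$shape, p0$shape, tolerance = 1e-12)
  expect_equal(p1$scale, p0$scale, tolerance = 1e-12)

  # prepending extra fully-masked steps changes nothing either
  d <- dim(ws$values)
  grown <- ws
  grown$values <- array(0, c(d[1], d[2] + 3, d[3]))
  grown$values[, 4:(d[2] + 3), ] <- ws$values
  grown$mask <- cbind(matrix(TRUE, d[1], 3), ws$mask)
  grown$horizon_steps <- d[2] + 3L
  p2 <- predict(fit, grown)
  expect_equal(p2$shape, p0$shape, tolerance = 1e-6)
  expect_equal(p2$scale, p0$scale, tolerance = 1e-6)
})

test_that("fully masked observations are refused", {
  fx <- tiny_cohort_windows(seed = 2)
  ws <- standardize_windows(fx$windows)
  ws$mask[1, ] <- TRUE
  cfg <- wtte_config(gru_units = 4, dense_units = 3, epochs = 1, seed = 1)
  expect_error(wtte_gru(ws, cfg), class = "wtte_data_error")
})

test_that("zero epochs returns an initialised model with empty history", {
  fx <- tiny_cohort_windows(seed = 6)
  cfg <- wtte_config(gru_units = 4, dense_units = 3, epochs = 0, seed = 2)
  fit <- wtte_gru(fx$windows, cfg)
  expect_equal(nrow(fit$history), 0)
  expect_equal(fit$best_epoch, 0)
  w0 <- wtteicu:::init_weights(
    dim(fx$windows$values)[3], cfg,
    mean_label = mean(fx$windows$labels$remaining_time)
  )
  for (nm in names(w0)) {
    expect_equal(as.numeric(fit$weights[[nm]]), as.numeric(w0[[nm]]))
  }
  p <- predict(fit, fx$windows)
  expect_true(all(p$shape > 0 & p$scale > 0))
})

test_that("training reduces the cost on a learnable problem", {
  fx <- tiny_cohort_windows(n_event = 15, n_censored = 25, seed = 14)
  costs_drop <- vapply(1:5, function(s) {
    cfg <- wtte_config(gru_units = 6, dense_units = 4, epochs = 10,
                       batch_size = 64, learning_rate = 0.01, seed = s)
    fit <- wtte_gru(fx$windows, cfg)
    h <- fit$history$train_cost
    utils::tail(h, 1) < h[1]
  }, logical(1))
  expect_true(all(costs_drop))
})

test_that("training is reproducible under a fixed seed", {
  fx <- tiny_cohort_windows(seed = 3)
  cfg <- wtte_config(gru_units = 5, dense_units = 3, epochs = 4,
                     batch_size = 64, seed = 11)
  f1 <- wtte_gru(fx$windows, cfg)
  f2 <- wtte_gru(fx$windows, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
})

test_that("stratified folds have balanced sizes and strata", {
  pats <- data.frame(patient_id = sprintf("P%03d", 1:759),
                     event = rep(c(1L, 0L), c(37, 722)))
  fold <- kfold_split(pats, 5, seed = 2)
  expect_true(all(table(fold) %in% c(151, 152)))
  ev_per_fold <- table(fold[pats$event == 1L])
  expect_true(all(ev_per_fold %in% c(7, 8)))
  expect_identical(fold, kfold_split(pats, 5, seed = 2))
  few <- data.frame(patient_id = c("a", "b", "c"),
                    event = c(1L, 0L, 0L))
  expect_error(kfold_split(few, 5), class = "wtte_data_error")
})

test_that("cross-validation predicts every observation exactly once, without leakage", {
  fx <- tiny_cohort_windows(n_event = 10, n_censored = 15, seed = 21)
  cfg <- wtte_config(gru_units = 5, dense_units = 3, epochs = 3,
                     batch_size = 128, n_folds = 3, seed = 4)
  cv <- run_cv(fx$windows, fx$patients, cfg)
  key <- paste(cv$predictions$patient_id, cv$predictions$prediction_hour)
  expect_equal(sort(key),
               sort(paste(fx$windows$labels$patient_id,
                          fx$windows$labels$prediction_hour)))
  expect_equal(nrow(cv$predictions), nrow(fx$windows$labels))
  # each patient's predictions come from exactly one fold
  by_pat <- tapply(cv$predictions$fold, cv$predictions$patient_id,
                   function(f) length(unique(f)))
  expect_true(all(by_pat == 1))
  # no leakage: each fold's scaler is a function of its training patients only
  for (f in seq_along(cv$fits)) {
    tr_obs <- which(cv$fold[fx$windows$labels$patient_id] != f)
    sc <- fit_scaler(subset_windows(fx$windows, tr_obs))
    expect_equal(cv$fits[[f]]$scaler$mean, sc$mean, tolerance = 1e-12)
    expect_equal(cv$fits[[f]]$scaler$sd, sc$sd, tolerance = 1e-12)
  }
})

test_that("model methods expose the fit in standard ways", {
  fx <- tiny_cohort_windows(seed = 17)
  cfg <- wtte_config(gru_units = 5, dense_units = 3, epochs = 3,
                     batch_size = 64, seed = 6)
  fit <- wtte_gru(fx$windows, cfg)
  expect_output(print(fit), "Recurrent Weibull")
  s <- summary(fit)
  expect_s3_class(s, "summary.wtte_gru")
  expect_output(print(s), "learnable parameters")
  expect_named(coef(fit), c("Wz", "Wr", "Wh", "Uz", "Ur", "Uh",
                            "bz", "br", "bh", "Wd", "bd", "Wo", "bo"))
  r <- residuals(fit)
  expect_length(r, nrow(fit$fitted))
  expect_true(all(r >= 0))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(nrow(fit$fitted), 2))
  expect_true(all(sim > 0))
  p_med <- predict(fit, fx$windows, type = "median")
  expect_equal(p_med$predicted_remaining,
               weib_median(p_med$shape, p_med$scale), tolerance = 1e-12)
  p_risk <- predict(fit, fx$windows, type = "risk", horizon = 8)
  expect_true(all(p_risk$risk >= 0 & p_risk$risk <= 1))
})

test_that("with no covariate signal, horizon discrimination sits at chance", {
  # 900 event patients give ~900 independent cases at the 1 h horizon, so
  # the null sampling error of the AUC is ~0.02 and the 0.45-0.55 band is
  # a meaningful assertion
  spec <- cohort_spec(n_event = 900, n_censored = 300, n_vars = 8,
                      hazard_weights = 0, drift_amplitude = 0,
                      true_shape = 1.5, baseline_scale = 20,
                      censor_median = 40,
                      missing_rate_hourly = 0, missing_rate_daily = 0,
                      daily_var_fraction = 0, seed = 37)
  coh <- generate_cohort(spec)
  feats <- suppressMessages(
    select_common_features(cohort_series_long(coh), sprintf("V%02d", 1:8))
  )
  pats <- cohort_patient_table(coh)
  win <- build_windows(feats, pats, horizon_steps = 8, tau = 72,
                       max_windows = 24, max_windows_censored = 24)
  cfg <- wtte_config(gru_units = 8, dense_units = 4, epochs = 30,
                     batch_size = 256, learning_rate = 0.003, seed = 11)
  # out-of-fold predictions: in-sample scores would reflect memorised
  # labels, not covariate signal
  cv <- run_cv(win, pats, cfg)
  tt <- suppressWarnings(tauc_table(cv$predictions, horizons = c(1, 8)))
  expect_true(all(tt$auc > 0.45 & tt$auc < 0.55))
})

test_that("a saved model round-trips with identical predictions", {
  fx <- tiny_cohort_windows(seed = 19)
  cfg <- wtte_config(gru_units = 5, dense_units = 3, epochs = 2,
                     batch_size = 64, seed = 8)
  fit <- wtte_gru(fx$windows, cfg)
  prefix <- file.path(withr::local_tempdir(), "model")
  paths <- write_wtte_model(fit, prefix)
  expect_true(all(file.exists(paths)))
  sidecar <- jsonlite::read_json(paths["sidecar"])
  expect_equal(sidecar$architecture$n_parameters,
               count_parameters(cfg, dim(fx$windows$values)[3]))
  back <- read_wtte_model(paths["model"])
  expect_equal(predict(back, fx$windows), predict(fit, fx$windows))
})
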