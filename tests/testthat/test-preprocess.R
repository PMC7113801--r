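# Feature selection, missingness filters, windowing and standardization.

test_that("pivot to the common-feature table is lossless and flags absences", {
  long <- data.frame(
    patient_id = rep(c("A", "B"), each = 4),
    hour = c(0, 0, 1, 1, 0, 0, 1, 1),
    variable = rep(c("hr", "sbp"), 4),
    value = 1:8
  )
  wide <- suppressMessages(select_common_features(long, c("hr", "sbp")))
  expect_equal(nrow(wide), 4)               # 2 patients x 2 hours
  expect_equal(sum(!is.na(wide[c("hr", "sbp")])), nrow(long))
  expect_equal(wide$hr[wide$patient_id == "A" & wide$hour == 1], 3)

  # a variable absent for one patient flags that patient only
  long2 <- long[!(long$patient_id == "B" & long$variable == "sbp"), ]
  expect_message(
    wide2 <- select_common_features(long2, c("hr", "sbp")),
    "missing at least one required variable"
  )
  expect_identical(attr(wide2, "flagged_patients"), "B")
  a_rows <- wide2[wide2$patient_id == "A", ]
  expect_true(all(!is.na(a_rows[c("hr", "sbp")])))
  expect_error(select_common_features(long, character(0)),
               class = "wtte_config_error")
})

test_that("missingness statistics count empty cells over the patient grid", {
  # 48 hours x 45 variables with 216 empty cells -> p_id 216, p_ir 0.1
  set.seed(11)
  vars <- sprintf("v%02d", 1:45)
  tab <- data.frame(patient_id = "A", hour = 0:47)
  for (v in vars) tab[[v]] <- 1.0
  holes <- cbind(sample(48, 216, replace = TRUE),
                 sample(45, 216, replace = TRUE))
  holes <- unique(holes)
  while (nrow(holes) < 216) {
    holes <- unique(rbind(holes, c(sample(48, 1), sample(45, 1))))
  }
  for (i in seq_len(216)) tab[holes[i, 1], vars[holes[i, 2]]] <- NA
  st <- compute_missingness(tab)
  expect_equal(st$p_id, 216)
  expect_equal(st$p_ir, 216 / 2160)

  # fully observed and fully missing boundaries
  full <- data.frame(patient_id = "B", hour = 0:9)
  for (v in vars) full[[v]] <- 2.0
  st_full <- compute_missingness(full)
  expect_equal(st_full$p_id, 0)
  expect_equal(st_full$p_ir, 0)
  empty <- full
  for (v in vars) empty[[v]] <- NA_real_
  st_empty <- compute_missingness(empty)
  expect_equal(st_empty$p_id, 450)
  expect_equal(st_empty$p_ir, 1)

  expect_error(compute_missingness(full, patients = c("B", "ghost")),
               "ghost", class = "wtte_data_error")
})

test_that("daily variables are assessed on their daily grid", {
  tab <- data.frame(patient_id = "A", hour = 0:47, hr = 1.0, lab = NA_real_)
  tab$lab[tab$hour %% 24 == 0] <- 5.0    # perfectly observed daily variable
  st <- compute_missingness(tab, daily_vars = "lab")
  expect_equal(st$p_id, 0)
  st_naive <- compute_missingness(tab)
  expect_equal(st_naive$p_id, 46)        # hourly reading would punish it
})

test_that("patients are filtered at the configured missingness thresholds", {
  st <- data.frame(
    patient_id = c("ok", "too_many", "too_sparse", "clean"),
    p_id = c(900, 1500, 100, 0),
    p_ir = c(0.19, 0.10, 0.25, 0)
  )
  expect_message(keep <- filter_patients(st), "too_many")
  expect_setequal(keep, c("ok", "clean"))
  # conservation: every patient is either retained or excluded, never both
  expect_equal(length(keep) + 2, nrow(st))
  expect_warning(none <- filter_patients(st, p_id_max = -1, quiet = TRUE),
                 "all patients excluded")
  expect_length(none, 0)
})

test_that("censored remaining times are capped at tau, events untouched", {
  expect_equal(cap_censored_tte(100, u = 0, tau = 72), 72)
  expect_equal(cap_censored_tte(100, u = 1, tau = 72), 100)
  expect_equal(cap_censored_tte(10, u = 0, tau = 72), 10)
  expect_equal(cap_censored_tte(c(10, 90, 90), u = c(0, 0, 1), tau = 72),
               c(10, 72, 90))
  expect_error(cap_censored_tte(5, 0, tau = -1), class = "wtte_config_error")
})

test_that("windows are right-aligned with masked left padding", {
  tab <- tiny_feature_table(n_hours = 3, vars = c("A", "B"))
  pats <- data.frame(patient_id = "P1", event = 0L, outcome_time = 3)
  ws <- build_windows(tab, pats, horizon_steps = 3, tau = 72)
  expect_equal(dim(ws$values), c(3, 3, 2))
  expect_equal(unname(rowSums(ws$mask)), c(2, 1, 0))
  # hand-enumerated contents: window at hour t ends with the hour-t vector
  expect_equal(ws$values[1, 3, ], c(A = 100, B = 200))
  expect_equal(ws$values[2, 2:3, "A"], c(100, 101))
  expect_equal(ws$values[3, , "B"], c(200, 201, 202))
  # the last unmasked step is the prediction hour itself
  for (o in 1:3) {
    last_live <- max(which(!ws$mask[o, ]))
    expect_equal(unname(ws$values[o, last_live, "A"]),
                 100 + ws$labels$prediction_hour[o])
  }
  expect_equal(ws$labels$remaining_time, c(3, 2, 1))
})

test_that("window contents match a brute-force sliding-window oracle", {
  # small random cohorts, windows enumerated by hand with in-window LOCF
  set.seed(99)
  for (rep in 1:3) {
    n_pat <- sample(2:5, 1)
    n_hours <- sample(3:6, 1)
    hs <- sample(2:4, 1)
    vars <- c("x", "y", "z")
    tab <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
      d <- data.frame(patient_id = paste0("P", i), hour = 0:(n_hours - 1))
      for (v in vars) {
        vals <- round(runif(n_hours), 3)
        vals[runif(n_hours) < 0.3] <- NA
        d[[v]] <- vals
      }
      d
    }))
    pats <- data.frame(patient_id = paste0("P", seq_len(n_pat)),
                       event = rep(c(1L, 0L), length.out = n_pat),
                       outcome_time = n_hours)
    ws <- build_windows(tab, pats, horizon_steps = hs, tau = 72)
    for (o in seq_len(nrow(ws$labels))) {
      pid <- ws$labels$patient_id[o]
      t <- ws$labels$prediction_hour[o]
      d <- tab[tab$patient_id == pid, ]
      expected <- matrix(NA_real_, hs, length(vars))
      expected_mask <- rep(TRUE, hs)
      for (s in seq_len(hs)) {
        h <- t - hs + s
        if (h < 0) next
        row <- d[d$hour == h, vars]
        expected_mask[s] <- all(is.na(row))
        for (j in seq_along(vars)) {
          # last observation carried forward inside the window only
          hist <- d[d$hour >= t - hs + 1 & d$hour <= h, vars[j]]
          hist <- hist[!is.na(hist)]
          expected[s, j] <- if (length(hist)) hist[length(hist)] else NA
        }
      }
      expect_equal(unname(ws$values[o, , ]), unname(expected))
      expect_equal(unname(ws$mask[o, ]), expected_mask)
    }
  }
})

test_that("event and censored patients anchor their window budgets differently", {
  tab <- tiny_feature_table(n_hours = 10, vars = c("A", "B"))
  pats <- data.frame(patient_id = "P1", event = 1L, outcome_time = 10)
  ws_ev <- build_windows(tab, pats, horizon_steps = 4, tau = 72,
                         max_windows = 4)
  # events keep the latest eligible hours: remaining times 4..1
  expect_equal(ws_ev$labels$prediction_hour, 6:9)
  expect_equal(ws_ev$labels$remaining_time, c(4, 3, 2, 1))

  pats$event <- 0L
  ws_ce <- build_windows(tab, pats, horizon_steps = 4, tau = 72,
                         max_windows = 4)
  # censored keep the earliest hours: large remaining-to-censoring
  expect_equal(ws_ce$labels$prediction_hour, 0:3)
  expect_equal(ws_ce$labels$remaining_time, c(10, 9, 8, 7))
})

test_that("event patients observed less than one hour pre-arrest are excluded", {
  tab <- tiny_feature_table(n_hours = 2, vars = c("A"))
  pats <- data.frame(patient_id = c("P1", "P2"),
                     event = c(1L, 1L), outcome_time = c(0.5, 2))
  tab2 <- tab; tab2$patient_id <- "P2"
  expect_warning(ws <- build_windows(rbind(tab, tab2), pats,
                                     horizon_steps = 2, tau = 72),
                 "before hour 1")
  expect_setequal(unique(ws$labels$patient_id), "P2")
  expect_true(all(ws$labels$remaining_time >= 1))
})

test_that("every censored label respects the cap over a whole generated set", {
  fx <- tiny_cohort_windows(seed = 8)
  lab <- fx$windows$labels
  expect_true(all(lab$remaining_time[lab$u == 0] <= fx$windows$tau))
  expect_true(all(lab$remaining_time > 0))
  # conservation: observation count equals the per-patient eligible sums
  expect_equal(nrow(lab), length(unique(paste(lab$patient_id, lab$prediction_hour))))
})

test_that("standardization centres training data and is invertible", {
  fx <- tiny_cohort_windows(seed = 4)
  ws <- fx$windows
  sc <- fit_scaler(ws)
  std <- standardize_windows(ws, sc)
  # training-fold means are zero over unmasked observed cells
  for (j in seq_len(dim(std$values)[3])) {
    cells_raw <- ws$values[, , j][!ws$mask]
    cells_std <- std$values[, , j][!std$mask]
    keep <- !is.na(cells_raw)
    expect_equal(mean(cells_std[keep]), 0, tolerance = 1e-10)
  }
  # round trip recovers observed cells to 1e-10
  back <- invert_scaler(std$values, sc)
  obs <- !is.na(ws$values)
  expect_equal(back[obs], ws$values[obs], tolerance = 1e-10)
  expect_error(standardize_windows(std, sc), class = "wtte_data_error")

  # validation data scaled with training statistics is generally off-centre
  fx2 <- tiny_cohort_windows(seed = 5)
  std2 <- standardize_windows(fx2$windows, sc)
  m2 <- vapply(seq_len(dim(std2$values)[3]), function(j) {
    cells <- std2$values[, , j][!std2$mask]
    mean(cells[cells != 0])
  }, numeric(1))
  expect_gt(max(abs(m2)), 1e-3)
})

test_that("a constant variable standardizes to zero, not NaN", {
  tab <- tiny_feature_table(n_hours = 4, vars = c("A", "B"))
  tab$B <- 7   # constant
  pats <- data.frame(patient_id = "P1", event = 0L, outcome_time = 4)
  ws <- build_windows(tab, pats, horizon_steps = 2, tau = 72)
  expect_warning(std <- standardize_windows(ws), "zero-variance")
  expect_true(all(is.finite(std$values)))
  expect_true(all(std$values[, , "B"][!std$mask] == 0))
})
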