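# evaluation: reference extraction, MAE/nMAE arithmetic, CV strategies,
# repositioning decomposition, agreement metrics.

test_that("reference events come from the GRF loading edges", {
  fs <- 100
  t <- (0:399) / fs
  f <- numeric(400)
  stance <- t > 1.0 & t < 1.7
  u <- (t[stance] - 1.0) / 0.7
  f[stance] <- 700 * sin(pi * u)
  g <- grf_trace(t, f, "left")
  ref <- extract_reference_events(g)
  expect_equal(ref$events$t[ref$events$kind == "IC"], 1.01, tolerance = 1 / fs)
  expect_equal(ref$events$t[ref$events$kind == "TO"], 1.70, tolerance = 1 / fs)

  # constant positive force: no events
  expect_equal(nrow(extract_reference_events(grf_trace(t, rep(1, 400), "left"))$events), 0)

  # two stances: interleaved IC/TO pairs
  f2 <- f + c(f[-(1:200)], f[1:200])
  ref2 <- extract_reference_events(grf_trace(t, f2, "left"))
  expect_equal(sum(ref2$events$kind == "IC"), 2)
  expect_equal(sum(ref2$events$kind == "TO"), 2)
  expect_equal(ref2$events$kind[order(ref2$events$t)],
               c("IC", "TO", "IC", "TO"))

  expect_error(extract_reference_events(grf_trace(t, numeric(400), "left")),
               class = "imugait_no_stance_error")

  # scenario ground truth supplies the mid-phase events
  ref3 <- extract_reference_events(g, ground_truth = list(MSt = 1.3, MSw = 2.1))
  expect_true(all(c("MSt", "MSw") %in% ref3$events$kind))
})

test_that("mean stride duration averages successive IC intervals", {
  es <- imugait:::new_event_series("left", rep("IC", 3), c(0, 1.2, 2.4))
  expect_equal(mean_stride_duration(es), 1.2)
  es2 <- imugait:::new_event_series("left", rep("IC", 3), c(0, 1.0, 2.4))
  expect_equal(mean_stride_duration(es2), 1.2)
  es1 <- imugait:::new_event_series("left", "IC", 1.0)
  expect_error(mean_stride_duration(es1),
               class = "imugait_insufficient_events_error")
})

test_that("timing error implements nearest-match MAE and nMAE", {
  mk <- function(tt) imugait:::new_event_series("left", rep("IC", length(tt)), tt)
  te <- timing_error(mk(c(1.02, 1.98)), mk(c(1.00, 2.00)), "IC",
                     stride_duration = 1.0)
  expect_equal(te$MAE, 0.02)
  expect_equal(te$nMAE, 2)

  expect_equal(timing_error(mk(c(1, 2)), mk(c(1, 2)), "IC",
                            stride_duration = 1)$nMAE, 0)

  # a missing detection inflates the error via nearest-match reuse
  te2 <- timing_error(mk(1.0), mk(c(1.0, 2.0)), "IC", stride_duration = 1.0)
  expect_equal(te2$MAE, 0.5)
  expect_equal(te2$nMAE, 50)

  # zero detected events: flagged undefined, not silently dropped
  te3 <- timing_error(mk(numeric(0)), mk(c(1, 2)), "IC", stride_duration = 1)
  expect_true(te3$undefined)
  expect_true(is.na(te3$nMAE))

  # shift equivariance
  sh <- 13.7
  te4 <- timing_error(mk(c(1.02, 1.98) + sh), mk(c(1.00, 2.00) + sh), "IC",
                      stride_duration = 1.0)
  expect_equal(te4$MAE, te$MAE)
  expect_equal(te4$nMAE, te$nMAE)
})

test_that("stride folds partition every stride exactly once", {
  ic <- seq(0, by = 1.2, length.out = 11)   # 10 strides
  ref <- imugait:::new_event_series("left", rep("IC", 11), ic)
  folds <- stride_folds(ref, 5)
  expect_length(folds, 5)
  widths <- vapply(folds, function(w) w[2] - w[1], 0)
  expect_equal(widths, rep(2.4, 5))  # 2 strides per fold
  # contiguous cover of the full span, no overlap
  expect_equal(folds[[1]][1], 0)
  for (i in 2:5) expect_equal(folds[[i]][1], folds[[i - 1]][2])
  expect_equal(folds[[5]][2], 12)
  expect_error(stride_folds(ref, 11), class = "imugait_strategy_error")
})

test_that("cross-validation tests every stride once and reports by fold", {
  pls <- list(leg_placement(6, 1))
  ds <- build_sim_dataset(gait_scenario(n_strides = 12, seed = 5), pls)
  rep <- crossval(ds, "A2a", phase_model = 2, k = 4)
  # every reference stride is tested exactly once
  for (side in c("left", "right")) {
    n_strides <- sum(ds$participants[[1]]$ref[[side]]$events$kind == "IC") - 1
    n_ic <- sum(rep$n_ref[rep$side == side & rep$event == "IC"])
    expect_equal(n_ic, n_strides)
  }
  expect_setequal(unique(rep$fold), 1:4)
  # noise-free world: held-out timing error stays small
  expect_lt(stats::median(rep$nMAE_pct, na.rm = TRUE), 3)
})

test_that("A2a equals A2c when all sensors of a segment are identical", {
  base <- leg_placement(6, 1)
  twin <- sensor_placement(base$segment_id, ring = 7, slot = 1,
                           offset_local = base$offset_local,
                           mount_rotation = base$mount_rotation,
                           azimuth = base$azimuth)
  ds <- build_sim_dataset(gait_scenario(n_strides = 10, seed = 8),
                          list(base, twin))
  ra <- crossval(ds, "A2a", phase_model = 4, k = 5)
  rc <- crossval(ds, "A2c", phase_model = 4, k = 5)
  key <- function(r) order(r$placement, r$side, r$event, r$fold)
  expect_equal(ra$nMAE_pct[key(ra)], rc$nMAE_pct[key(rc)], tolerance = 1e-12)
})

test_that("identical participants make A2b match A2a", {
  pls <- list(leg_placement(6, 1))
  ds <- build_sim_dataset(gait_scenario(n_strides = 10, seed = 3), pls,
                          n_participants = 2)
  # force exchangeability: both participants share one realisation
  ds$participants[[2]] <- ds$participants[[1]]
  ra <- crossval(ds, "A2a", phase_model = 2, k = 5)
  rb <- crossval(ds, "A2b", phase_model = 2)
  ma <- stats::median(ra$nMAE_pct, na.rm = TRUE)
  mb <- stats::median(rb$nMAE_pct, na.rm = TRUE)
  expect_lt(abs(ma - mb), 2)
  expect_error(crossval(structure(list(participants = ds$participants[1],
                                       placement_ids = ds$placement_ids),
                                  class = "gait_dataset"), "A2b"),
               class = "imugait_strategy_error")
})

test_that("rotatory/translatory decomposition summarises rings and slots", {
  # constant error surface: both IQRs zero
  rep <- data.frame(segment = "lower_leg", ring = rep(1:12, each = 16),
                    slot = rep(1:16, 12), nMAE_pct = 5)
  rt <- rot_trans_errors(rep)
  expect_equal(rt$rotatory$IQR, 0)
  expect_equal(rt$translatory$IQR, 0)
  expect_equal(rt$rotatory$median, 5)

  # error varying only with azimuth: rotatory IQR > 0, translatory = 0
  rep$nMAE_pct <- 5 + 3 * sin(2 * pi * rep$slot / 16)
  rt2 <- rot_trans_errors(rep)
  expect_gt(rt2$rotatory$IQR, 0)
  expect_equal(rt2$translatory$IQR, 0)

  rep$segment <- "shoe"
  expect_error(rot_trans_errors(rep), class = "imugait_unsupported_grid_error")
})

test_that("agreement metrics pool correlations through Fisher's z", {
  x <- sin(seq(0, 10, by = 0.01))
  same <- list(list(measured = x, synthesised = x),
               list(measured = x + 1, synthesised = x + 1))
  m <- agreement_metrics(same)
  expect_equal(m$r_mean, 1, tolerance = 1e-6)
  expect_equal(m$MAD, 0)
  expect_equal(m$RMSE, 0)
  expect_equal(m$nMAD, 0)

  anti <- list(list(measured = x, synthesised = -x))
  expect_equal(agreement_metrics(anti)$r_mean, -1, tolerance = 1e-6)

  # two participants with r = 0.5 and 0.8 pool to tanh(mean(atanh(r)))
  set.seed(1)
  mk_pair <- function(r, n = 4000) {
    a <- stats::rnorm(n)
    b <- r * a + sqrt(1 - r^2) * stats::rnorm(n)
    # enforce the sample correlation exactly via residual orthogonalisation
    b <- r * scale(a)[, 1] + sqrt(1 - r^2) *
      scale(stats::residuals(stats::lm(b ~ a)))[, 1]
    list(measured = a, synthesised = b)
  }
  pr <- list(mk_pair(0.5), mk_pair(0.8))
  m2 <- agreement_metrics(pr)
  expect_equal(m2$per_participant_r, c(0.5, 0.8), tolerance = 1e-10)
  expect_equal(m2$r_mean, tanh((atanh(0.5) + atanh(0.8)) / 2),
               tolerance = 1e-10)
  expect_true(m2$r_ci[1] < m2$r_mean && m2$r_mean < m2$r_ci[2])

  const <- list(list(measured = rep(1, 10), synthesised = 1:10))
  expect_true(agreement_metrics(const)$undefined)
})

test_that("error reports export and plot", {
  pls <- list(leg_placement(1, 1), leg_placement(1, 9))
  ds <- build_sim_dataset(gait_scenario(n_strides = 8, seed = 6), pls)
  rep <- crossval(ds, "A2a", phase_model = 1, k = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_error_report(rep, path)
  df <- utils::read.csv(path)
  expect_true(all(c("segment", "ring", "slot", "event", "nMAE_pct") %in% names(df)))
  expect_equal(nrow(df), nrow(rep))
  png_path <- withr::local_tempfile(fileext = ".png")
  plot_error_report(rep, png_path)
  expect_true(file.exists(png_path))
})
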