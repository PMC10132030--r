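# gait_detection: peak detection, threshold training, sign changes, the
# A1/A2 event rules and the cyclic phase-model machine.

test_that("detect_peaks matches its worked examples", {
  x <- c(0, 1, 0, 2, 0)
  pk <- detect_peaks(x, fs = 1, theta_h = 0.5, theta_d = 1, polarity = "+")
  expect_equal(pk$i, c(2, 4))
  expect_equal(pk$h, c(1, 2))

  expect_equal(nrow(detect_peaks(rep(1, 50), fs = 100)), 0)

  t <- (0:499) / 100
  s <- sin(2 * pi * t)          # 1 Hz over 5 s
  pk <- detect_peaks(s, t = t, theta_h = 0.5, theta_d = 0.6, polarity = "+")
  expect_equal(nrow(pk), 5)

  # negative polarity is positive detection on -x
  pkn <- detect_peaks(-s, t = t, theta_h = -0.5, theta_d = 0.6, polarity = "-")
  expect_equal(pkn$t, pk$t)
  expect_equal(pkn$h, -pk$h)
})

test_that("distance conflicts keep the more extreme peak", {
  # two peaks 0.3 s apart above threshold: only the higher survives
  t <- (0:99) / 100
  x <- numeric(100)
  x[21] <- 1.0
  x[51] <- 1.4
  pk <- detect_peaks(x, t = t, theta_h = 0.5, theta_d = 0.6, polarity = "+")
  expect_equal(pk$i, 51)
  # ties resolved to the earlier peak
  x[51] <- 1.0
  pk2 <- detect_peaks(x, t = t, theta_h = 0.5, theta_d = 0.6, polarity = "+")
  expect_equal(pk2$i, 21)
})

test_that("detect_peaks equals the brute-force oracle on random signals", {
  set.seed(123)
  for (rep in 1:40) {
    n <- sample(50:400, 1)
    x <- as.numeric(stats::filter(stats::rnorm(n), rep(1 / 4, 4), sides = 1))
    x[is.na(x)] <- 0
    fs <- 100
    t <- (seq_len(n) - 1) / fs
    th <- stats::quantile(x, stats::runif(1, 0.5, 0.95))
    td <- stats::runif(1, 0, 0.3)
    pol <- sample(c("+", "-"), 1)
    got <- detect_peaks(x, t = t, theta_h = if (pol == "+") th else -th,
                        theta_d = td, polarity = pol)
    want <- oracle_peaks(x, t, theta_h = if (pol == "+") th else -th,
                         theta_d = td, polarity = pol)
    expect_identical(got$i, want)
  }
})

test_that("raising theta_h never increases the peak count", {
  set.seed(5)
  x <- as.numeric(stats::filter(stats::rnorm(500), rep(0.2, 5), sides = 1))
  x[is.na(x)] <- 0
  counts <- vapply(seq(-1, 1.5, by = 0.25), function(th)
    nrow(detect_peaks(x, fs = 100, theta_h = th, theta_d = 0.05)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("fit_theta_h implements the fractional-mean rule", {
  # candidate heights {1, 2, 3}, fraction 0.15 -> 2 - 0.3
  t <- (0:999) / 100
  x <- numeric(1000)
  x[c(101, 401, 701)] <- c(1, 2, 3)
  expect_equal(fit_theta_h(x, t = t, polarity = "+", fraction = 0.15), 1.7)

  # negative: heights {-1, -3} -> -2 + 0.3
  xn <- numeric(1000)
  xn[c(201, 901)] <- c(-1, -3)
  expect_equal(fit_theta_h(xn, t = t, polarity = "-", fraction = 0.15), -1.7)

  # single candidate h: theta = h (1 - fraction)
  x1 <- numeric(300); x1[150] <- 2.4
  expect_equal(fit_theta_h(x1, fs = 100, polarity = "+", fraction = 0.25),
               2.4 * 0.75)

  expect_error(fit_theta_h(rep(0, 100), fs = 100, polarity = "+"),
               class = "imugait_training_error")
})

test_that("sign_changes is strict", {
  expect_equal(sign_changes(c(0.5, -0.2), fs = 1), 1)
  expect_length(sign_changes(c(-1, 1), fs = 1), 0)
  expect_length(sign_changes(c(1, 0, -1), fs = 1), 0)
})

test_that("the IC pairing rule obeys the ordered 50 ms window", {
  fs <- 100
  t <- (0:399) / fs
  base <- detection_params(1)
  base$theta_h$ic_accel <- 0.5
  mk_w <- function(tc) ifelse(t < tc, 0.5, -0.5)  # one +/- change at tc
  mk_a <- function(tp) { a <- numeric(400); a[round(tp * fs) + 1] <- 1; a }

  # change at 1.00, peak at 1.03 -> IC at 1.03
  ev <- detect_ic_a2(mk_a(1.03), mk_w(1.00), t, base)
  expect_equal(ev$events$t, 1.03)
  # peak at 1.06 -> outside the window
  expect_equal(nrow(detect_ic_a2(mk_a(1.06), mk_w(1.00), t, base)$events), 0)
  # peak precedes the change -> none
  expect_equal(nrow(detect_ic_a2(mk_a(0.97), mk_w(1.00), t, base)$events), 0)
  # simultaneity allowed (closed window start)
  expect_equal(detect_ic_a2(mk_a(1.00), mk_w(1.00), t, base)$events$t, 1.00)
  expect_error(detect_ic_a2(numeric(10), numeric(9), t, base),
               class = "imugait_alignment_error")
})

test_that("the TO pairing rule requires accel trough then gyro trough", {
  fs <- 100
  t <- (0:399) / fs
  base <- detection_params(2)
  base$theta_h$to_accel <- -0.5
  base$theta_h$to_gyro <- -0.5
  dip <- function(tc) { x <- numeric(400); x[round(tc * fs) + 1] <- -1; x }

  ev <- detect_to_a2(dip(1.40), dip(1.43), t, base)
  expect_equal(ev$events$t, 1.43)
  expect_equal(ev$events$kind, "TO")
  expect_equal(nrow(detect_to_a2(dip(1.43), dip(1.40), t, base)$events), 0)
  expect_equal(nrow(detect_to_a2(dip(1.40), dip(1.48), t, base)$events), 0)
})

test_that("the mid-phase gradient gate accepts quiet windows only", {
  fs <- 100
  t <- (0:599) / fs
  base <- detection_params(4)
  base$theta_h$msw_gyro <- 0.5
  base$grad_tol_contra <- 0.05
  w <- numeric(600); w[301] <- 1

  # flat contralateral acceleration: accepted
  ev <- detect_msw_a2(w, rep(9.81, 600), t, base)
  expect_equal(ev$events$t, 3.00)
  expect_equal(ev$events$kind, "MSw")

  # an impact transient inside the gate window: rejected
  a_noisy <- rep(9.81, 600)
  a_noisy[300] <- 12
  expect_equal(nrow(detect_msw_a2(w, a_noisy, t, base)$events), 0)

  expect_error(detect_msw_a2(w, NULL, t, base),
               class = "imugait_bipedal_input_error")

  base$theta_h$mst_gyro <- 0.5
  base$grad_tol_ipsi <- 0.05
  expect_equal(detect_mst_a2(w, rep(9.81, 600), t, base)$events$kind, "MSt")
  expect_equal(nrow(detect_mst_a2(numeric(600), rep(9.81, 600), t, base)$events), 0)
  expect_error(detect_mst_a2(NULL, rep(9.81, 600), t, base),
               class = "imugait_bipedal_input_error")
})

test_that("4-phase detection finds one event of each kind per stride", {
  pr <- fix_imu_pair()
  prm <- fix_trained()
  ev <- run_phase_model(pr$left, pr$right, "A2", prm$left, prm$right)
  for (side in c("left", "right")) {
    gt <- interior_gt(pr$scn, side)
    es <- ev[[side]]$events
    for (kind in c("IC", "MSt", "TO", "MSw")) {
      det <- es$t[es$kind == kind]
      inwin <- det[det >= gt$window[1] & det < gt$window[2]]
      expect_equal(length(inwin), length(gt[[kind]]),
                   info = sprintf("%s %s", side, kind))
    }
    # cyclic order holds
    expect_true(all(diff(es$t) > 0))
    kinds <- es$kind
    cyc <- c("IC", "MSt", "TO", "MSw")
    start <- match(kinds[1], cyc)
    expect_equal(kinds,
                 cyc[((start - 1 + seq_along(kinds) - 1) %% 4) + 1])
  }
})

test_that("all reported event times lie on the input time grid", {
  pr <- fix_imu_pair()
  prm <- fix_trained()
  ev <- run_phase_model(pr$left, pr$right, "A2", prm$left, prm$right)
  expect_true(all(ev$left$events$t %in% pr$left$t))
  expect_true(all(ev$right$events$t %in% pr$right$t))
})

test_that("A1 and A2 agree on IC cadence for clean 1-phase input", {
  scn <- fix_scenario20()
  gu <- build_leg_grid("upper_leg", 0.45, 0.08)
  pl <- Filter(function(p) p$ring == 6 && p$slot == 1, gu$placements)[[1]]
  iL <- scenario_imu(scn, pl, "left"); iR <- scenario_imu(scn, pl, "right")
  b1 <- detection_params(1)
  tl <- train_detection_params(iL$a[, 2], iL$omega[, 3], iL$t, b1)
  tr <- train_detection_params(iR$a[, 2], iR$omega[, 3], iR$t, b1)
  e1 <- run_phase_model(iL, iR, "A1", tl, tr)
  e2 <- run_phase_model(iL, iR, "A2", tl, tr)
  gt <- interior_gt(scn, "left")
  w <- gt$window
  count_in <- function(es) sum(es$events$t >= w[1] & es$events$t < w[2])
  expect_equal(count_in(e1$left), count_in(e2$left))
  expect_equal(count_in(e1$left), length(gt$IC))
})

test_that("unsupported combinations and empty input are handled", {
  pr <- fix_imu_pair()
  prm <- fix_trained()
  expect_error(run_phase_model(pr$left, pr$right, "A1", prm$left, prm$right),
               class = "imugait_unsupported_combination_error")

  empty <- pr$left
  empty$t <- numeric(0)
  empty$a <- empty$a[0, , drop = FALSE]
  empty$omega <- empty$omega[0, , drop = FALSE]
  ev <- run_phase_model(empty, empty, "A2", prm$left, prm$right)
  expect_equal(nrow(ev$left$events), 0)
})

test_that("sub-threshold signals yield no events", {
  t <- (0:299) / 100
  base <- detection_params(1)
  base$theta_h$ic_accel <- 5
  x <- 0.1 * sin(2 * pi * t)
  expect_equal(nrow(detect_ic_a1(x, t, base)$events), 0)
})

test_that("events CSV export round-trips", {
  pr <- fix_imu_pair()
  prm <- fix_trained()
  ev <- run_phase_model(pr$left, pr$right, "A2", prm$left, prm$right)
  path <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(ev, path)
  df <- utils::read.csv(path)
  expect_equal(names(df), c("side", "kind", "t_seconds"))
  expect_equal(nrow(df), nrow(ev$left$events) + nrow(ev$right$events))
})
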