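# Shared fixtures, built once per test run and memoised in this
# environment.  Everything is generated in code; no data files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small noise-free symmetric scenario (10 strides)
fix_scenario <- function() {
  cached("scn10", function()
    generate_scenario(gait_scenario(n_strides = 10, jitter_sd = 0, seed = 7)))
}

# jittered 20-stride scenario for detection/evaluation tests
fix_scenario20 <- function() {
  cached("scn20", function()
    generate_scenario(gait_scenario(n_strides = 20, seed = 11)))
}

fix_leg_grid <- function() cached("legg", function() build_leg_grid("lower_leg", 0.43, 0.055))

leg_placement <- function(ring = 6, slot = 1, grid = fix_leg_grid()) {
  Filter(function(p) p$ring == ring && p$slot == slot, grid$placements)[[1]]
}

# synthesised bilateral IMU pair for a placement on the 20-stride scenario
fix_imu_pair <- function(ring = 6, slot = 1) {
  key <- sprintf("imu_%d_%d", ring, slot)
  cached(key, function() {
    scn <- fix_scenario20()
    pl <- leg_placement(ring, slot)
    list(left = scenario_imu(scn, pl, "left"),
         right = scenario_imu(scn, pl, "right"),
         placement = pl, scn = scn)
  })
}

fix_trained <- function(ring = 6, slot = 1, phase_model = 4) {
  key <- sprintf("trained_%d_%d_%d", ring, slot, phase_model)
  cached(key, function() {
    pr <- fix_imu_pair(ring, slot)
    base <- detection_params(phase_model)
    tr <- function(i, c) train_detection_params(i$a[, 2], i$omega[, 3], i$t, base,
                                                a_y_contra = c$a[, 2],
                                                omega_z_contra = c$omega[, 3])
    list(left = tr(pr$left, pr$right), right = tr(pr$right, pr$left))
  })
}

# a constant-pose sensor trajectory (upright, stationary)
static_sensor <- function(n = 200, fs = 100) {
  structure(list(t = (seq_len(n) - 1) / fs,
                 k = matrix(rep(c(0, 1, 0), each = n), n, 3),
                 Q = array(diag(3), c(3, 3, n)), fs = fs,
                 placement = sensor_placement("lower_leg", 1, 1, c(0, 0, 0))),
            class = "sensor_trajectory")
}

# planar rotation about global z at a constant rate (rad/s)
spinning_sensor <- function(rate = 1, n = 301, fs = 100, radius = 0) {
  t <- (seq_len(n) - 1) / fs
  Q <- array(0, c(3, 3, n))
  k <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    th <- rate * t[i]
    Q[, , i] <- t(imugait:::rot_z(th))
    k[i, ] <- c(radius * cos(th), radius * sin(th), 0)
  }
  structure(list(t = t, k = k, Q = Q, fs = fs,
                 placement = sensor_placement("lower_leg", 1, 1, c(0, 0, 0))),
            class = "sensor_trajectory")
}

# brute-force peak-detection oracle: enumerate strict local extrema,
# filter by height, then greedy removal by extremity (ties: earlier time)
oracle_peaks <- function(x, t, theta_h = NULL, theta_d = 0.6,
                         polarity = "+") {
  w <- if (polarity == "+") x else -x
  idx <- integer(0)
  for (i in seq_along(w)[-c(1, length(w))])
    if (w[i] > w[i - 1] && w[i] > w[i + 1]) idx <- c(idx, i)
  if (!is.null(theta_h)) {
    th <- if (polarity == "+") theta_h else -theta_h
    idx <- idx[w[idx] >= th]
  }
  kept <- integer(0)
  for (i in idx[order(-w[idx], t[idx])]) {
    ok <- TRUE
    for (j in kept) if (abs(t[i] - t[j]) < theta_d) ok <- FALSE
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# interior ground-truth events (first and last stride discarded), plus the
# matching evaluation window for detected events: it starts just before
# the first interior IC and ends just before the first non-interior IC, so
# detected events of the last interior stride (timestamps sit up to
# ~50 ms after their anchors) are still inside.
interior_gt <- function(scn, side) {
  gt <- scn$ground_truth[[side]]
  lo <- gt$IC[2]; hi <- gt$IC[length(gt$IC)]
  out <- lapply(gt, function(x) x[x >= lo & x < hi])
  out$window <- c(lo - 0.06, hi - 0.06)
  out
}
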