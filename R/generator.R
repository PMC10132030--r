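# Synthetic bilateral gait generator.
#
# Produces planar (sagittal) lower-limb pose trajectories for six segments
# (upper leg, lower leg, shoe x left/right), a synthetic vertical GRF per
# side, and exact ground-truth gait events (IC, MSt, TO, MSw), so the
# synthesis + detection + evaluation pipeline is fully testable without
# any external motion data.
#
# Construction principle: the detectors consume only the morphology of the
# vertical acceleration a_y and sagittal angular velocity w_z around the
# four events.  The generator therefore anchors the canonical segment
# angular-RATE profile directly in stride phase: w crosses zero from + to -
# at IC, has its (dominant) trough at TO and its (dominant) positive peak
# at mid swing; segment angles are the (periodic, zero-mean) integral of
# that rate.  Vertical impact/push-off transients are injected as Gaussian
# acceleration pulses on the hip trajectory (centre IC + 20 ms, and TO -
# 20 ms), so accelerometer peaks land where the event rules expect them.
# Ground-truth events are the anchor phases themselves.

#' Gait scenario parameters
#'
#' Defines the stated world of the synthetic generator.  Defaults emulate
#' moderately impaired treadmill walking: 1.2 s mean stride, 62 % stance,
#' small stride-duration jitter, and a configurable per-side timing
#' asymmetry for hemiparesis-like gait.
#'
#' @param n_strides Strides per body side.
#' @param stride_duration Mean stride duration (s).
#' @param jitter_sd Standard deviation of stride-duration jitter (s).
#' @param stance_fraction Fraction of the stride spent in stance, in (0,1).
#' @param asymmetry Multiplier on the affected side's stride (and hence
#'   stance) duration; 1 = symmetric.
#' @param affected_side Side the asymmetry multiplier applies to.
#' @param amplitude Named vector of sagittal angle peak-to-peak amplitudes
#'   (rad) per segment class (`upper_leg`, `lower_leg`, `shoe`).
#' @param noise_sd Kinematic noise: standard deviation (rad) of 6 Hz
#'   low-passed angle noise added to every segment angle (0 = noise-free).
#' @param fs Sampling rate (Hz).
#' @param seed RNG seed; identical parameters + seed give bit-identical
#'   output.
#' @param upper_length,lower_length Segment lengths (m).
#' @param hip_height Hip joint height (m).
#' @param impact_dip Depth (m) of the Gaussian hip dip at loading
#'   response; its analytic second derivative is the accelerometer's
#'   impact transient (a low-frequency Ricker wavelet that survives the
#'   filter chain), with a matching hip rise at push-off.
#' @param impact_delay Centre of the IC dip after the IC anchor (s).
#' @param impact_sigma Gaussian width of the dips (s).
#' @param pushoff_lead Centre of the push-off rise before the TO anchor
#'   (s).
#' @return An object of class `gait_scenario`.
#' @export
gait_scenario <- function(n_strides = 20, stride_duration = 1.2,
                          jitter_sd = 0.03, stance_fraction = 0.62,
                          asymmetry = 1, affected_side = "left",
                          amplitude = c(upper_leg = 0.32, lower_leg = 0.55,
                                        shoe = 0.75),
                          noise_sd = 0, fs = 100, seed = 1,
                          upper_length = 0.45, lower_length = 0.43,
                          hip_height = 0.95,
                          impact_dip = 0.085, impact_delay = 0.020,
                          impact_sigma = 0.055, pushoff_lead = 0.020) {
  if (stance_fraction <= 0 || stance_fraction >= 1)
    imugait_stop("scenario_error", "stance_fraction must lie in (0,1)")
  if (stride_duration <= 2 * 0.15)
    imugait_stop("scenario_error",
                 "stride_duration must exceed twice the 4-phase wait time (0.3 s)")
  structure(as.list(environment()), class = "gait_scenario")
}

# ---------------------------------------------------------------------------
# Canonical sagittal angular-rate profile, anchored in stride phase.

# Periodic Gaussian-free construction: shape-defining knots -> periodic
# spline -> lobe balancing (zero mean, so the integrated angle is periodic)
# -> truncated Fourier projection (smooth, analytic integral).
make_rate_profile <- function(stance_fraction = 0.62, n_harmonics = 14,
                              n_grid = 4096) {
  sf <- stance_fraction
  if (sf < 0.2 || sf > 0.8)
    imugait_stop("scenario_error",
                 "stance_fraction %.3g outside the representable band [0.2, 0.8] (profile anchors collide)",
                 sf)
  msw <- (1 + sf) / 2            # mid-swing anchor
  z0 <- (sf + msw) / 2           # -/+ crossing between TO and MSw
  knots_x <- c(0, 0.08, sf / 2, sf - 0.08, sf, z0, msw, msw + 0.06,
               1 - 0.04, 1)
  knots_y <- c(0, -0.70, -0.55, -0.90, -1.60, 0, 2.20, 1.20, 0.35, 0)
  f <- stats::splinefun(knots_x, knots_y, method = "periodic")
  phi <- (seq_len(n_grid) - 1) / n_grid
  w <- f(phi)
  pos <- pmax(w, 0); neg <- pmin(w, 0)
  lambda <- -mean(neg) / mean(pos)
  w <- neg + lambda * pos
  k <- seq_len(n_harmonics)
  ak <- 2 * colMeans(w * cos(2 * pi * outer(phi, k)))
  bk <- 2 * colMeans(w * sin(2 * pi * outer(phi, k)))
  # normalise so the integrated angle has unit peak-to-peak amplitude
  theta <- drop(sin(2 * pi * outer(phi, k)) %*% (ak / (2 * pi * k)) -
                cos(2 * pi * outer(phi, k)) %*% (bk / (2 * pi * k)))
  scale <- 1 / (max(theta) - min(theta))
  list(ak = ak * scale, bk = bk * scale, k = k,
       stance_fraction = sf, msw = msw)
}

profile_rate <- function(pr, phi) {
  drop(cos(2 * pi * outer(phi, pr$k)) %*% pr$ak +
       sin(2 * pi * outer(phi, pr$k)) %*% pr$bk)
}

profile_angle <- function(pr, phi) {
  drop(sin(2 * pi * outer(phi, pr$k)) %*% (pr$ak / (2 * pi * pr$k)) -
       cos(2 * pi * outer(phi, pr$k)) %*% (pr$bk / (2 * pi * pr$k)))
}

smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

# Piecewise-linear stride phase: phi(b_i) = i exactly; linear in between
# and linearly extrapolated outside with the edge stride rate.
phase_of_time <- function(t, boundaries) {
  n <- length(boundaries) - 1
  i <- findInterval(t, boundaries)
  i <- pmin(pmax(i, 1), n)
  (i - 1) + (t - boundaries[i]) / (boundaries[i + 1] - boundaries[i])
}

#' Generate a synthetic gait scenario
#'
#' Builds the full bilateral fixture: six segment trajectories, two GRF
#' traces and exact ground-truth events.  Deterministic for a fixed
#' parameter set and seed.
#'
#' @param sc A [gait_scenario()].
#' @return A list with elements `trajectories` (named list of six
#'   [segment_trajectory()]s), `grf` (list `left`/`right` of
#'   [grf_trace()]s), `ground_truth` (per side: numeric vectors `IC`,
#'   `MSt`, `TO`, `MSw` in seconds), `scenario` and `profile`.
#' @export
#' @examples
#' scn <- generate_scenario(gait_scenario(n_strides = 4, seed = 7))
#' names(scn$trajectories)
#' length(scn$ground_truth$left$IC)
generate_scenario <- function(sc) {
  stopifnot(inherits(sc, "gait_scenario"))
  set.seed(sc$seed)
  pr <- make_rate_profile(sc$stance_fraction)
  sides <- c("left", "right")
  # Stride boundaries are anchored to a per-side metronome (treadmill-like
  # phase locking): boundary jitter is independent per boundary, not a
  # random walk, so the two sides cannot drift apart.  Boundary noise sd
  # jitter_sd/sqrt(2) yields stride-duration sd ~ jitter_sd.
  bsd <- sc$jitter_sd / sqrt(2)
  clamp <- min(3 * bsd, 0.2 * sc$stride_duration)
  bounds <- list(); durs <- list()
  for (side in sides) {
    mult <- if (side == sc$affected_side) sc$asymmetry else 1
    eps <- pmin(pmax(stats::rnorm(sc$n_strides + 1, 0, bsd), -clamp), clamp)
    eps[1] <- 0
    off <- if (side == "left") 0 else 0.5 * sc$stride_duration
    bounds[[side]] <- off + (0:sc$n_strides) * sc$stride_duration * mult + eps
    durs[[side]] <- diff(bounds[[side]])
  }
  tmax <- min(vapply(bounds, max, 0))
  t <- seq(0, tmax, by = 1 / sc$fs)
  nt <- length(t)

  # ground truth from the anchors, clipped to the simulated span
  gt <- list()
  for (side in sides) {
    b <- bounds[[side]]; d <- durs[[side]]
    ic <- b[-length(b)]
    ev <- list(IC = ic,
               MSt = ic + 0.5 * sc$stance_fraction * d,
               TO = ic + sc$stance_fraction * d,
               MSw = ic + (1 + sc$stance_fraction) / 2 * d)
    ev <- lapply(ev, function(x) x[x >= 0 & x <= tmax])
    gap <- diff(sort(unlist(ev)))
    if (length(gap) && min(gap) < 2 / sc$fs)
      imugait_stop("scenario_error",
                   "infeasible timing: events closer than 2 samples")
    gt[[side]] <- ev
  }

  prefilter <- butter2_lowpass(6, sc$fs)
  noise_angle <- function() {
    if (sc$noise_sd <= 0) return(numeric(nt))
    z <- filtfilt2(stats::rnorm(nt), prefilter)
    z / stats::sd(z) * sc$noise_sd
  }

  trajectories <- list(); grf <- list()
  amp <- sc$amplitude
  for (side in sides) {
    phi <- phase_of_time(t, bounds[[side]])
    th_can <- profile_angle(pr, phi %% 1)

    # hip trajectory with impact / push-off transients: a Gaussian dip of
    # the hip at loading response (depth impact_dip, width impact_sigma)
    # and a matching rise at push-off.  The second time derivative of a
    # Gaussian dip is a low-frequency Ricker wavelet with positive central
    # peak dip/sigma^2 at the dip centre -- the accelerometer's impact
    # transient -- while velocity and position stay bounded per event.
    bump <- numeric(nt)
    sig <- sc$impact_sigma
    for (tic in gt[[side]]$IC)
      bump <- bump - sc$impact_dip *
        exp(-(t - tic - sc$impact_delay)^2 / (2 * sig^2))
    for (tto in gt[[side]]$TO)
      bump <- bump + sc$impact_dip *
        exp(-(t - tto + sc$pushoff_lead)^2 / (2 * sig^2))

    zhip <- if (side == "left") -0.10 else 0.10
    hip <- cbind(0.02 * sin(2 * pi * phi),
                 sc$hip_height + 0.012 * cos(4 * pi * phi) + bump,
                 zhip)

    th <- list(upper_leg = amp[["upper_leg"]] * th_can + noise_angle(),
               lower_leg = amp[["lower_leg"]] * th_can + noise_angle(),
               shoe = amp[["shoe"]] * th_can + noise_angle())

    knee <- hip + sc$upper_length * cbind(sin(th$upper_leg), -cos(th$upper_leg), 0)
    ankle <- knee + sc$lower_length * cbind(sin(th$lower_leg), -cos(th$lower_leg), 0)
    origins <- list(upper_leg = hip, lower_leg = knee, shoe = ankle)

    for (seg in names(origins)) {
      Q <- array(0, c(3, 3, nt))
      ang <- th[[seg]]
      ca <- cos(ang); sa <- sin(ang)
      Q[1, 1, ] <- ca; Q[1, 2, ] <- sa
      Q[2, 1, ] <- -sa; Q[2, 2, ] <- ca
      Q[3, 3, ] <- 1
      trajectories[[paste0(seg, "_", side)]] <-
        segment_trajectory(t, Q, origins[[seg]], paste0(seg, "_", side))
    }

    # trapezoid-like smooth GRF pulse per stance, strictly positive inside
    f <- numeric(nt)
    ics <- gt[[side]]$IC; tos <- gt[[side]]$TO
    for (i in seq_along(ics)) {
      if (i > length(tos)) break
      u <- (t - ics[i]) / (tos[i] - ics[i])
      inside <- u > 0 & u < 1
      f[inside] <- f[inside] +
        700 * smoothstep(u[inside] / 0.15) * smoothstep((1 - u[inside]) / 0.15)
    }
    grf[[side]] <- grf_trace(t, f, side)
  }

  list(trajectories = trajectories, grf = grf, ground_truth = gt,
       scenario = sc, profile = pr)
}

#' Write a generated scenario to canonical-dialect files
#'
#' Emits one trajectory file per segment and one GRF file per side into
#' `dir`, all readable by [load_pose_trajectory()] / [load_grf_trace()].
#'
#' @param scn Output of [generate_scenario()].
#' @param dir Output directory (created if missing).
#' @return Character vector of the written paths, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(scn$trajectories)) {
    p <- file.path(dir, paste0(nm, ".sto"))
    write_pose_trajectory(scn$trajectories[[nm]], p)
    paths <- c(paths, p)
  }
  for (side in names(scn$grf)) {
    p <- file.path(dir, paste0("grf_", side, ".sto"))
    write_grf_trace(scn$grf[[side]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Synthesise the IMU signal of one placement in a scenario
#'
#' Convenience wrapper: attaches `placement` to the matching segment
#' trajectory of `side` and runs the synthesis chain.
#'
#' @param scn Output of [generate_scenario()].
#' @param placement A [sensor_placement()].
#' @param side `"left"` or `"right"`.
#' @param spec A [filter_spec()].
#' @param smooth Apply the Savitzky--Golay stage.
#' @return An `imu_signal`.
#' @export
scenario_imu <- function(scn, placement, side, spec = filter_spec(),
                         smooth = TRUE) {
  base <- sub("_(left|right)$", "", placement$segment_id)
  traj <- scn$trajectories[[paste0(base, "_", side)]]
  if (is.null(traj))
    imugait_stop("attachment_error", "scenario has no segment `%s_%s`", base, side)
  synthesize_imu(sensor_world_trajectory(traj, placement), spec, smooth)
}
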