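# Threshold-based gait event detection.
#
# Building blocks: a peak detector parameterised by a minimum height
# theta_h and a minimum inter-peak distance theta_d (conflicts resolved in
# favour of the more extreme peak, ties by earlier time); threshold
# training that derives theta_h as a fraction of the mean candidate peak
# height; a strict positive-to-negative sign-change detector; and the
# event rules:
#
#   A1  IC: positive peaks of a_y (accelerometer only), theta_d = 0.6 s.
#   A2  IC: gyro +/- sign change followed by a qualifying a_y peak within
#       50 ms (event time = the accel peak).
#   A2  TO: negative a_y peak followed by a negative gyro peak within
#       50 ms (event time = the gyro trough).
#   A2 MSw: positive ipsilateral gyro peak while the CONTRAlateral a_y is
#       locally quiet (gradient gate).
#   A2 MSt: positive CONTRAlateral gyro peak while the ipsilateral a_y is
#       locally quiet; assigned to the ipsilateral timeline.
#
# A cyclic state machine (run_phase_model) enforces the 1-/2-/4-phase
# event order with event-specific wait-time anchors.

#' Detection parameters
#'
#' @param phase_model 1, 2 or 4 (events `{IC}`, `{IC,TO}`,
#'   `{IC,MSt,TO,MSw}`).
#' @param theta_d Minimum distance between two same-kind events (s).
#' @param accel_fraction,gyro_fraction Threshold fractions of the mean
#'   candidate peak height (0.15 for acceleration, 0.25 for gyroscope).
#' @param pair_window Two-condition pairing window (s).
#' @param grad_window Gradient-gate segment length t_d (s).
#' @param grad_quantile Gradient-gate tolerance quantile.
#' @param gyro_sign Sign applied to the gyro channel before detection
#'   (+1/-1); part of position-dependent parameterisation (see
#'   [train_detection_params()]).
#' @return An object of class `detection_params`.  The wait time `t_w` is
#'   derived from the phase model: 0.6 s (1-phase), 0.3 s (2-phase),
#'   0.15 s (4-phase).
#' @export
detection_params <- function(phase_model = 4, theta_d = 0.6,
                             accel_fraction = 0.15, gyro_fraction = 0.25,
                             pair_window = 0.05, grad_window = 0.05,
                             grad_quantile = 0.75, gyro_sign = 1) {
  if (!phase_model %in% c(1, 2, 4))
    imugait_stop("config_error", "phase_model must be 1, 2 or 4")
  t_w <- c(`1` = 0.6, `2` = 0.3, `4` = 0.15)[[as.character(phase_model)]]
  structure(list(phase_model = phase_model, t_w = t_w, theta_d = theta_d,
                 accel_fraction = accel_fraction,
                 gyro_fraction = gyro_fraction, pair_window = pair_window,
                 grad_window = grad_window, grad_quantile = grad_quantile,
                 gyro_sign = gyro_sign,
                 theta_h = list()),
            class = "detection_params")
}

#' Peak detection with height and distance thresholds
#'
#' Local extrema of the requested polarity (`"+"`: strict local maxima
#' with height `>= theta_h`; `"-"`: implemented as positive detection on
#' `-x`, i.e. local minima with height `<= theta_h`).  When two candidates
#' lie closer than `theta_d`, the more extreme one survives (ties: earlier
#' time), as in the conventional findpeaks semantics.
#'
#' @param x Numeric signal.
#' @param t Timestamps (s), or `NULL` with `fs` given.
#' @param fs Sampling rate, used when `t` is `NULL`.
#' @param theta_h Minimum peak height (`NULL` = no height gate, used for
#'   candidate collection during training).
#' @param theta_d Minimum distance between surviving peaks (s).
#' @param polarity `"+"` or `"-"`.
#' @return A data.frame with columns `t`, `h` (height in the original
#'   signal's units/sign) and `i` (sample index), ordered by time.
#' @export
detect_peaks <- function(x, t = NULL, fs = NULL, theta_h = NULL,
                         theta_d = 0.6, polarity = c("+", "-")) {
  polarity <- match.arg(polarity)
  if (is.null(t)) {
    if (is.null(fs)) imugait_stop("config_error", "need t or fs")
    t <- (seq_along(x) - 1) / fs
  }
  if (theta_d < 0) imugait_stop("config_error", "theta_d must be >= 0")
  w <- if (polarity == "+") x else -x
  n <- length(w)
  if (n < 3) return(data.frame(t = numeric(0), h = numeric(0), i = integer(0)))
  cand <- which(w[2:(n - 1)] > w[1:(n - 2)] & w[2:(n - 1)] > w[3:n]) + 1L
  if (!is.null(theta_h)) {
    th <- if (polarity == "+") theta_h else -theta_h
    cand <- cand[w[cand] >= th]
  }
  if (length(cand) > 1 && theta_d > 0) {
    ord <- cand[order(-w[cand], t[cand])]
    keep <- logical(0)
    kept_t <- numeric(0)
    for (i in ord) {
      if (all(abs(t[i] - kept_t) >= theta_d)) kept_t <- c(kept_t, t[i])
    }
    cand <- sort(cand[t[cand] %in% kept_t])
  }
  data.frame(t = t[cand], h = x[cand], i = cand)
}

#' Train the minimum peak height
#'
#' Runs candidate peak detection without a height gate (distance gate
#' only), averages the candidate heights, and derives the threshold as a
#' fraction of that mean: `h_bar - |h_bar| * fraction` for positive
#' polarity, `h_bar + |h_bar| * fraction` for negative polarity.
#'
#' @inheritParams detect_peaks
#' @param fraction Threshold fraction (0.15 accel, 0.25 gyro).
#' @param windows Optional list of `c(t0, t1)` training windows; candidate
#'   peaks outside all windows are ignored.
#' @return The trained `theta_h` (scalar).
#' @export
fit_theta_h <- function(x, t = NULL, fs = NULL, polarity = c("+", "-"),
                        fraction = 0.15, theta_d = 0.6, windows = NULL) {
  polarity <- match.arg(polarity)
  pk <- detect_peaks(x, t = t, fs = fs, theta_h = NULL, theta_d = theta_d,
                     polarity = polarity)
  if (!is.null(windows)) {
    inw <- rep(FALSE, nrow(pk))
    for (w in windows) inw <- inw | (pk$t >= w[1] & pk$t < w[2])
    pk <- pk[inw, ]
  }
  if (nrow(pk) == 0)
    imugait_stop("training_error", "no candidate peaks in the training data")
  h_bar <- mean(pk$h)
  if (polarity == "+") h_bar - abs(h_bar) * fraction
  else h_bar + abs(h_bar) * fraction
}

#' Positive-to-negative sign changes
#'
#' Timestamps `t[i]` with `x[i-1] > 0` and `x[i] < 0` (strict; an exact
#' zero breaks eligibility).
#'
#' @inheritParams detect_peaks
#' @return Numeric vector of timestamps.
#' @export
sign_changes <- function(x, t = NULL, fs = NULL) {
  if (is.null(t)) {
    if (is.null(fs)) imugait_stop("config_error", "need t or fs")
    t <- (seq_along(x) - 1) / fs
  }
  n <- length(x)
  if (n < 2) return(numeric(0))
  t[which(x[-n] > 0 & x[-1] < 0) + 1]
}

# Max |second-order central difference| within [tc - w/2, tc + w/2].
window_gradient_stat <- function(x, t, tc, width) {
  n <- length(x)
  d2 <- c(0, abs(x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]), 0)
  sel <- t >= tc - width / 2 & t <= tc + width / 2
  if (!any(sel)) return(Inf)
  max(d2[sel])
}

# Tolerance: the grad_quantile quantile of the per-window statistic over
# consecutive grad_window segments of the (training portion of the) trial.
gradient_tolerance <- function(x, t, params, windows = NULL) {
  width <- params$grad_window
  n_per <- max(2L, round(width * 1 / mean(diff(t))))
  starts <- seq(1, length(x) - n_per + 1, by = n_per)
  stat <- vapply(starts, function(s) {
    seg <- x[s:(s + n_per - 1)]
    if (n_per < 3) return(0)
    max(abs(seg[3:n_per] - 2 * seg[2:(n_per - 1)] + seg[1:(n_per - 2)]))
  }, 0)
  if (!is.null(windows)) {
    tc <- t[starts] + width / 2
    inw <- rep(FALSE, length(starts))
    for (w in windows) inw <- inw | (tc >= w[1] & tc < w[2])
    if (any(inw)) stat <- stat[inw]
  }
  stats::quantile(stat, params$grad_quantile, names = FALSE)
}

#' Train algorithm parameters on (a portion of) a trial
#'
#' Fits every threshold the A1/A2 rules need from training data: the
#' gyro-sign calibration (position-dependent parameterisation; the sign
#' making the dominant angular-velocity extremum positive), the
#' accelerometer IC/TO thresholds, the gyroscope TO/MSw thresholds, the
#' contralateral-gyro MSt threshold and the gradient-gate tolerances.
#'
#' @param a_y Ipsilateral vertical (sensor y) acceleration.
#' @param omega_z Ipsilateral sensor z angular velocity (rad/s).
#' @param a_y_contra,omega_z_contra Contralateral channels (needed for the
#'   4-phase rules; may be `NULL` for 1-/2-phase).
#' @param t Timestamps (s).
#' @param params A [detection_params()] template.
#' @param windows Optional list of training windows `c(t0, t1)`.
#' @param calibrate_sign Train the per-sensor gyro sign (TRUE for
#'   position-dependent variants; FALSE fixes +1).
#' @return `params` with `theta_h` (named list), `grad_tol`, `gyro_sign`
#'   (and `gyro_sign_contra`) filled in.
#' @export
train_detection_params <- function(a_y, omega_z, t, params = detection_params(),
                                   a_y_contra = NULL, omega_z_contra = NULL,
                                   windows = NULL, calibrate_sign = TRUE) {
  sgn_of <- function(w) {
    if (!calibrate_sign || is.null(w)) return(1)
    if (all(w == 0)) return(1)
    if (w[which.max(abs(w))] > 0) 1 else -1
  }
  s_ipsi <- sgn_of(omega_z)
  w_ipsi <- if (is.null(omega_z)) NULL else s_ipsi * omega_z
  th <- list()
  th$ic_accel <- fit_theta_h(a_y, t = t, polarity = "+",
                             fraction = params$accel_fraction,
                             theta_d = params$theta_d, windows = windows)
  if (!is.null(w_ipsi) && params$phase_model >= 2) {
    th$to_accel <- fit_theta_h(a_y, t = t, polarity = "-",
                               fraction = params$accel_fraction,
                               theta_d = params$theta_d, windows = windows)
    th$to_gyro <- fit_theta_h(w_ipsi, t = t, polarity = "-",
                              fraction = params$gyro_fraction,
                              theta_d = params$theta_d, windows = windows)
  }
  out <- params
  if (params$phase_model == 4) {
    th$msw_gyro <- fit_theta_h(w_ipsi, t = t, polarity = "+",
                               fraction = params$gyro_fraction,
                               theta_d = params$theta_d, windows = windows)
    if (!is.null(omega_z_contra)) {
      s_con <- sgn_of(omega_z_contra)
      th$mst_gyro <- fit_theta_h(s_con * omega_z_contra, t = t, polarity = "+",
                                 fraction = params$gyro_fraction,
                                 theta_d = params$theta_d, windows = windows)
      out$gyro_sign_contra <- s_con
    }
    if (!is.null(a_y_contra))
      out$grad_tol_contra <- gradient_tolerance(a_y_contra, t, params, windows)
    out$grad_tol_ipsi <- gradient_tolerance(a_y, t, params, windows)
  }
  out$gyro_sign <- s_ipsi
  out$theta_h <- th
  out
}

# --- candidate-level rules (no cross-kind wait times) ----------------------

ic_candidates_a1 <- function(a_y, t, params) {
  detect_peaks(a_y, t = t, theta_h = params$theta_h$ic_accel,
               theta_d = params$theta_d, polarity = "+")$t
}

ic_candidates_a2 <- function(a_y, w, t, params) {
  sc <- sign_changes(w, t = t)
  pk <- detect_peaks(a_y, t = t, theta_h = params$theta_h$ic_accel,
                     theta_d = params$theta_d, polarity = "+")$t
  keep <- vapply(pk, function(tp)
    any(tp - sc >= 0 & tp - sc <= params$pair_window), NA)
  pk[keep]
}

to_candidates_a2 <- function(a_y, w, t, params) {
  pa <- detect_peaks(a_y, t = t, theta_h = params$theta_h$to_accel,
                     theta_d = params$theta_d, polarity = "-")$t
  pw <- detect_peaks(w, t = t, theta_h = params$theta_h$to_gyro,
                     theta_d = params$theta_d, polarity = "-")$t
  keep <- vapply(pw, function(tg)
    any(tg - pa >= 0 & tg - pa <= params$pair_window), NA)
  pw[keep]
}

msw_candidates_a2 <- function(w_ipsi, a_contra, t, params) {
  pk <- detect_peaks(w_ipsi, t = t, theta_h = params$theta_h$msw_gyro,
                     theta_d = params$theta_d, polarity = "+")$t
  tol <- params$grad_tol_contra
  keep <- vapply(pk, function(tp)
    window_gradient_stat(a_contra, t, tp, params$grad_window) <= tol, NA)
  pk[keep]
}

mst_candidates_a2 <- function(w_contra, a_ipsi, t, params) {
  pk <- detect_peaks(w_contra, t = t, theta_h = params$theta_h$mst_gyro,
                     theta_d = params$theta_d, polarity = "+")$t
  tol <- params$grad_tol_ipsi
  keep <- vapply(pk, function(tp)
    window_gradient_stat(a_ipsi, t, tp, params$grad_window) <= tol, NA)
  pk[keep]
}

new_event_series <- function(side, kind = character(0), t = numeric(0),
                             phase_model = 4) {
  structure(list(side = side,
                 events = data.frame(kind = kind, t = t),
                 phase_model = phase_model),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %s (%d-phase): %s\n", x$side, x$phase_model,
              paste(sprintf("%d %s", table(x$events$kind)[unique(x$events$kind)],
                            unique(x$events$kind)), collapse = ", ")))
  invisible(x)
}

# --- standalone detector operations (spec surface) -------------------------

as_events <- function(times, kind, side, phase_model) {
  new_event_series(side, rep(kind, length(times)), times, phase_model)
}

#' Standalone event detectors
#'
#' Single-rule detectors applying their own same-kind distance constraint
#' (their trained `theta_h` must be present in `params$theta_h`; see
#' [train_detection_params()]).  `run_phase_model()` combines the same
#' rules under the cross-kind cyclic wait-time machine.
#'
#' @param a_y Vertical (sensor y) acceleration (ipsilateral unless noted).
#' @param omega_z Sensor z angular velocity, sign-corrected scale as
#'   trained (ipsilateral unless noted).
#' @param t Timestamps (s).
#' @param params Trained [detection_params()].
#' @param side Side label for the returned events.
#' @return An `event_series`.
#' @export
detect_ic_a1 <- function(a_y, t, params, side = "left") {
  as_events(ic_candidates_a1(a_y, t, params), "IC", side, params$phase_model)
}

#' @rdname detect_ic_a1
#' @export
detect_ic_a2 <- function(a_y, omega_z, t, params, side = "left") {
  if (length(a_y) != length(omega_z))
    imugait_stop("alignment_error", "a_y and omega_z lengths differ")
  as_events(ic_candidates_a2(a_y, params$gyro_sign * omega_z, t, params),
            "IC", side, params$phase_model)
}

#' @rdname detect_ic_a1
#' @export
detect_to_a2 <- function(a_y, omega_z, t, params, side = "left") {
  if (length(a_y) != length(omega_z))
    imugait_stop("alignment_error", "a_y and omega_z lengths differ")
  as_events(to_candidates_a2(a_y, params$gyro_sign * omega_z, t, params),
            "TO", side, params$phase_model)
}

#' @rdname detect_ic_a1
#' @param omega_z_ipsi,a_y_contra MSw inputs: ipsilateral gyro and
#'   contralateral acceleration.
#' @export
detect_msw_a2 <- function(omega_z_ipsi, a_y_contra, t, params, side = "left") {
  if (is.null(a_y_contra))
    imugait_stop("bipedal_input_error", "MSw detection needs the contralateral acceleration")
  as_events(msw_candidates_a2(params$gyro_sign * omega_z_ipsi, a_y_contra,
                              t, params),
            "MSw", side, params$phase_model)
}

#' @rdname detect_ic_a1
#' @param omega_z_contra,a_y_ipsi MSt inputs: contralateral gyro and
#'   ipsilateral acceleration.
#' @export
detect_mst_a2 <- function(omega_z_contra, a_y_ipsi, t, params, side = "left") {
  if (is.null(omega_z_contra))
    imugait_stop("bipedal_input_error", "MSt detection needs the contralateral gyro")
  sgn <- if (!is.null(params$gyro_sign_contra)) params$gyro_sign_contra else 1
  as_events(mst_candidates_a2(sgn * omega_z_contra, a_y_ipsi, t, params),
            "MSt", side, params$phase_model)
}

# --- cyclic state machine --------------------------------------------------

phase_cycle <- function(phase_model) {
  switch(as.character(phase_model),
         `1` = "IC", `2` = c("IC", "TO"), `4` = c("IC", "MSt", "TO", "MSw"))
}

run_state_machine <- function(cand, params) {
  # cand: data.frame(kind, t), time-sorted; returns accepted data.frame
  cyc <- phase_cycle(params$phase_model)
  expected_i <- 1
  last_t <- c(IC = -Inf, MSt = -Inf, TO = -Inf, MSw = -Inf)
  last_event <- -Inf
  acc_kind <- character(0); acc_t <- numeric(0)
  for (r in seq_len(nrow(cand))) {
    kind <- cand$kind[r]; tt <- cand$t[r]
    if (kind != cyc[expected_i]) next
    # same-kind spacing (the 1-phase wait time)
    if (tt - last_t[[kind]] < 0.6 - 1e-9) next
    ok <- switch(kind,
      IC = if (params$phase_model == 1) TRUE
           else tt - last_event >= params$t_w - 1e-9,
      TO = tt - last_event >= params$t_w - 1e-9,
      MSw = !is.finite(last_t[["IC"]]) || tt - last_t[["IC"]] >= params$t_w - 1e-9,
      MSt = !is.finite(last_t[["TO"]]) || tt - last_t[["TO"]] >= params$t_w - 1e-9)
    if (!ok) next
    acc_kind <- c(acc_kind, kind); acc_t <- c(acc_t, tt)
    last_t[[kind]] <- tt; last_event <- tt
    expected_i <- expected_i %% length(cyc) + 1
  }
  data.frame(kind = acc_kind, t = acc_t)
}

#' Run a full phase-model detection on a bilateral sensor pair
#'
#' Collects the candidate events of every rule active under the requested
#' phase model and algorithm, then enforces the cyclic event order
#' (IC -> MSt -> TO -> MSw for the 4-phase model) with the event-specific
#' wait-time anchors: IC waits on the previous IC (1-phase) or the
#' previous event (2-/4-phase); TO waits on the previous event; MSw waits
#' on the last IC; MSt waits on the last TO.  Out-of-order candidates are
#' skipped, not reordered (missing peaks surface as missing events).
#'
#' @param imu_left,imu_right `imu_signal`s of the same placement on the
#'   left/right segment.
#' @param algo `"A1"` (acceleration only; 1-phase only) or `"A2"`.
#' @param params_left,params_right Trained [detection_params()] per side.
#' @return List with `left` and `right` `event_series`.
#' @export
run_phase_model <- function(imu_left, imu_right, algo = c("A2", "A1"),
                            params_left, params_right = params_left) {
  algo <- match.arg(algo)
  pm <- params_left$phase_model
  if (algo == "A1" && pm != 1)
    imugait_stop("unsupported_combination_error",
                 "A1 is defined for the 1-phase model only")
  out <- list()
  for (side in c("left", "right")) {
    ipsi <- if (side == "left") imu_left else imu_right
    contra <- if (side == "left") imu_right else imu_left
    params <- if (side == "left") params_left else params_right
    t <- ipsi$t
    if (length(t) == 0) {
      out[[side]] <- new_event_series(side, phase_model = pm)
      next
    }
    ay <- ipsi$a[, 2]
    w <- params$gyro_sign * ipsi$omega[, 3]
    cand <- data.frame(kind = character(0), t = numeric(0))
    add <- function(cand, kind, times)
      rbind(cand, data.frame(kind = rep(kind, length(times)), t = times))
    if (algo == "A1") {
      cand <- add(cand, "IC", ic_candidates_a1(ay, t, params))
    } else {
      cand <- add(cand, "IC", ic_candidates_a2(ay, w, t, params))
      if (pm >= 2)
        cand <- add(cand, "TO", to_candidates_a2(ay, w, t, params))
      if (pm == 4) {
        sgn_c <- if (!is.null(params$gyro_sign_contra)) params$gyro_sign_contra else 1
        wc <- sgn_c * contra$omega[, 3]
        cand <- add(cand, "MSw", msw_candidates_a2(w, contra$a[, 2], t, params))
        cand <- add(cand, "MSt", mst_candidates_a2(wc, ay, t, params))
      }
    }
    cand <- cand[order(cand$t), ]
    acc <- run_state_machine(cand, params)
    out[[side]] <- new_event_series(side, acc$kind, acc$t, pm)
  }
  out
}

#' Export detected events as CSV
#'
#' @param series List of `event_series` (e.g. from [run_phase_model()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(series, path) {
  rows <- do.call(rbind, lapply(series, function(es)
    if (nrow(es$events)) data.frame(side = es$side, kind = es$events$kind,
                                    t_seconds = es$events$t) else NULL))
  if (is.null(rows))
    rows <- data.frame(side = character(0), kind = character(0),
                       t_seconds = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
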