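# Signal conditioning: order-2 Butterworth low-pass (bilinear transform),
# zero-phase forward-backward application, and a Savitzky-Golay smoother.
# Implemented from the closed forms; no external signal-processing package
# is required at run time.

#' Filter specification for IMU signal conditioning
#'
#' Bundles the cut-off frequencies and smoother settings applied to
#' synthesised signals before event detection: a second-order Butterworth
#' low-pass at 17 Hz for acceleration and 15 Hz for angular velocity,
#' followed by an optional Savitzky--Golay smoother (polynomial order 5,
#' window 35 samples) to remove outliers.  A 6 Hz low-pass is carried along
#' for pre-filtering raw kinematic (marker-level) input.
#'
#' @param accel_cutoff Acceleration low-pass cut-off in Hz.
#' @param gyro_cutoff Angular-velocity low-pass cut-off in Hz.
#' @param butter_order Butterworth order (only 2 is implemented).
#' @param sg_order Savitzky--Golay polynomial order.
#' @param sg_window Savitzky--Golay window length in samples (odd,
#'   `> sg_order`).
#' @param marker_cutoff Kinematic pre-filter cut-off in Hz.
#' @param zero_phase Apply filters forward-backward (zero phase lag).  The
#'   causal mode (`FALSE`) is provided for completeness; event-timing
#'   comparisons assume the default.
#' @return An object of class `filter_spec`.
#' @export
#' @examples
#' fs <- filter_spec()
#' fs$accel_cutoff
filter_spec <- function(accel_cutoff = 17, gyro_cutoff = 15, butter_order = 2,
                        sg_order = 5, sg_window = 35, marker_cutoff = 6,
                        zero_phase = TRUE) {
  if (butter_order != 2)
    imugait_stop("filter_error", "only the order-2 Butterworth is implemented")
  if (sg_window %% 2 == 0 || sg_window <= sg_order)
    imugait_stop("filter_error", "Savitzky-Golay window must be odd and exceed the order")
  structure(list(accel_cutoff = accel_cutoff, gyro_cutoff = gyro_cutoff,
                 butter_order = butter_order, sg_order = sg_order,
                 sg_window = sg_window, marker_cutoff = marker_cutoff,
                 zero_phase = zero_phase),
            class = "filter_spec")
}

#' Second-order Butterworth low-pass coefficients
#'
#' Digital coefficients via the bilinear transform with frequency
#' pre-warping.  Returns `b` (moving-average) and `a` (autoregressive,
#' `a[1] == 1`) for the difference equation
#' `y[n] = b1 x[n] + b2 x[n-1] + b3 x[n-2] - a2 y[n-1] - a3 y[n-2]`.
#'
#' @param cutoff Cut-off frequency in Hz.
#' @param fs Sampling rate in Hz; `cutoff` must be below `fs/2`.
#' @return List with numeric vectors `b` and `a` (length 3 each).
#' @export
butter2_lowpass <- function(cutoff, fs) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    imugait_stop("filter_error", "cutoff must lie in (0, fs/2); got %g at fs = %g", cutoff, fs)
  K <- tan(pi * cutoff / fs)
  s2 <- sqrt(2)
  d <- 1 + s2 * K + K^2
  b0 <- K^2 / d
  list(b = c(b0, 2 * b0, b0),
       a = c(1, 2 * (K^2 - 1) / d, (1 - s2 * K + K^2) / d))
}

# One-pass IIR filtering (direct form II transposed equivalent),
# zero initial conditions.
iir_filter <- function(x, b, a) {
  n <- length(x)
  xp <- c(0, 0, x)
  z <- b[1] * xp[3:(n + 2)] + b[2] * xp[2:(n + 1)] + b[3] * xp[1:n]
  as.numeric(stats::filter(z, -a[-1], method = "recursive"))
}

#' Zero-phase filtering
#'
#' Applies an IIR filter forward and backward with odd-symmetric edge
#' padding (as conventional for offline, phase-sensitive analyses), so
#' filtered extrema keep their timestamps.
#'
#' @param x Numeric vector.
#' @param coef List with `b` and `a`, e.g. from [butter2_lowpass()].
#' @return Filtered vector, same length as `x`.
#' @export
filtfilt2 <- function(x, coef) {
  n <- length(x)
  pad <- min(n - 1, 3 * 3 * (length(coef$a)))
  if (pad < 1) {
    y <- iir_filter(x, coef$b, coef$a)
    return(rev(iir_filter(rev(y), coef$b, coef$a)))
  }
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  xe <- c(pre, x, post)
  y <- iir_filter(xe, coef$b, coef$a)
  y <- rev(iir_filter(rev(y), coef$b, coef$a))
  y[(pad + 1):(pad + n)]
}

#' Savitzky--Golay smoothing
#'
#' Least-squares local polynomial smoother.  Interior samples use the
#' standard convolution weights; the first and last half-windows are
#' replaced by evaluations of polynomials fitted to the edge windows, so no
#' samples are lost.
#'
#' @param x Numeric vector.
#' @param order Polynomial order.
#' @param window Odd window length in samples, `> order`.
#' @return Smoothed vector, same length as `x`.
#' @export
savgol <- function(x, order = 5, window = 35) {
  n <- length(x)
  if (window %% 2 == 0 || window <= order)
    imugait_stop("filter_error", "window must be odd and exceed the polynomial order")
  if (window >= n)
    imugait_stop("filter_error", "Savitzky-Golay window (%d) must be shorter than the series (%d)", window, n)
  m <- (window - 1) / 2
  A <- outer(-m:m, 0:order, `^`)
  # weights reproducing the fitted value at the window centre
  w <- solve(crossprod(A), t(A))[1, ]
  y <- stats::filter(x, rev(w), sides = 2)
  y <- as.numeric(y)
  # polynomial edge handling
  head_fit <- stats::lm.fit(A, x[1:window])$coefficients
  tail_fit <- stats::lm.fit(A, x[(n - window + 1):n])$coefficients
  idx <- 1:m
  y[idx] <- drop(outer(idx - m - 1, 0:order, `^`) %*% head_fit)
  y[n - m + idx] <- drop(outer(idx, 0:order, `^`) %*% tail_fit)
  y
}
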