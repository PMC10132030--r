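# Virtual IMU signal synthesis from a sensor world trajectory.
#
# The additive accelerometer model: the total sensor-frame specific force
# is the sum of the dynamic acceleration (second time derivative of the
# sensor's world position, rotated into the sensor frame) and the gravity
# share (projection of the global gravity axis j = (0,1,0) onto the sensor
# axes, scaled by g = 9.81 m/s^2).  Angular velocity is extracted from the
# skew-symmetric matrix Q * d(Q')/dt of the sensor's global->sensor
# rotation stream, giving the body-frame (sensor-frame) rate vector.
# Internal units are m/s^2 and rad/s; degrees only appear at reporting
# boundaries.

GRAVITY <- 9.81

central_diff <- function(x, dt) {
  # first derivative, second-order central with first-order one-sided edges
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

second_diff <- function(x, dt) {
  # second derivative, central in the interior, copied one-sided at edges
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
  d[1] <- (x[3] - 2 * x[2] + x[1]) / dt^2
  d[n] <- (x[n] - 2 * x[n - 1] + x[n - 2]) / dt^2
  d
}

#' Dynamic acceleration of a sensor
#'
#' Second time derivative of the sensor world position (central
#' differences; one-sided at the edges), rotated into the sensor frame.
#'
#' @param st A `sensor_trajectory` (see [sensor_world_trajectory()]), at
#'   least 5 samples.
#' @return `n x 3` matrix of sensor-frame dynamic acceleration (m/s^2).
#' @export
dynamic_acceleration <- function(st) {
  n <- length(st$t)
  if (n < 5) imugait_stop("insufficient_data_error",
                          "need >= 5 samples for dynamic acceleration, got %d", n)
  dt <- 1 / st$fs
  kdd <- apply(st$k, 2, second_diff, dt = dt)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) out[i, ] <- st$Q[, , i] %*% kdd[i, ]
  out
}

#' Gravity share of a sensor
#'
#' Projection of the global gravity axis onto the sensor axes:
#' `a_g(t) = Q_s(t) %*% c(0, 1, 0) * g`.  Its Euclidean norm equals g at
#' every sample, by rotation invariance.
#'
#' @param st A `sensor_trajectory`.
#' @param g Gravitational acceleration (m/s^2).
#' @return `n x 3` matrix of sensor-frame gravity acceleration (m/s^2).
#' @export
gravity_acceleration <- function(st, g = GRAVITY) {
  n <- length(st$t)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) out[i, ] <- st$Q[, , i][, 2] * g
  out
}

#' Sensor-frame angular velocity
#'
#' Extracts the rate vector from the skew-symmetric matrix
#' `S(t) = Q(t) %*% d(Q(t)')/dt` (central-difference derivative), i.e. the
#' rigid-body angular velocity expressed in the sensor frame.  For planar
#' sagittal motion the z component equals the segment's signed sagittal
#' angular rate (positive for a rotation carrying local x towards local
#' y).
#'
#' @param st A `sensor_trajectory`, at least 3 samples.
#' @return `n x 3` matrix of angular velocity (rad/s).
#' @export
angular_velocity <- function(st) {
  n <- length(st$t)
  if (n < 3) imugait_stop("insufficient_data_error",
                          "need >= 3 samples for angular velocity, got %d", n)
  dt <- 1 / st$fs
  # aliasing guard: per-sample rotation increment must stay below pi/2
  for (i in seq_len(n - 1)) {
    tr <- sum(diag(st$Q[, , i + 1] %*% t(st$Q[, , i])))
    ang <- acos(min(1, max(-1, (tr - 1) / 2)))
    if (ang > pi / 2)
      imugait_stop("aliasing_error",
                   "rotation increment %.3g rad at sample %d exceeds pi/2", ang, i)
  }
  Qd <- array(0, c(3, 3, n))
  Qd[, , 2:(n - 1)] <- (st$Q[, , 3:n] - st$Q[, , 1:(n - 2)]) / (2 * dt)
  Qd[, , 1] <- (st$Q[, , 2] - st$Q[, , 1]) / dt
  Qd[, , n] <- (st$Q[, , n] - st$Q[, , n - 1]) / dt
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) out[i, ] <- unskew(st$Q[, , i] %*% t(Qd[, , i]))
  out
}

#' Convert angular velocity to degrees per second
#' @param omega Angular velocity in rad/s (vector or matrix).
#' @return Same shape, in deg/s.
#' @export
rad_to_deg_s <- function(omega) omega * 180 / pi

#' Synthesise a full IMU signal
#'
#' Assembles the additive accelerometer model (dynamic + gravity, computed
#' on the unfiltered orientation stream), then applies the conditioning
#' chain to the summed channels: a zero-phase order-2 Butterworth low-pass
#' (17 Hz acceleration / 15 Hz gyroscope) and, optionally, a
#' Savitzky--Golay smoother (order 5, window 35).
#'
#' @param st A `sensor_trajectory` at the 100 Hz default contract (any
#'   uniform rate is accepted; cut-offs must stay below Nyquist).
#' @param spec A [filter_spec()].
#' @param smooth Apply the Savitzky--Golay stage.
#' @return An object of class `imu_signal` with fields `t`, `fs`, `a`
#'   (filtered `n x 3` acceleration, m/s^2), `omega` (filtered `n x 3`
#'   angular velocity, rad/s), and the unfiltered components `a_dyn`,
#'   `a_grav`, `omega_raw` (so `a_dyn + a_grav` reproduces the raw additive
#'   model samplewise).
#' @export
synthesize_imu <- function(st, spec = filter_spec(), smooth = TRUE) {
  a_d <- dynamic_acceleration(st)
  a_g <- gravity_acceleration(st)
  om <- angular_velocity(st)
  a <- a_d + a_g
  n <- nrow(a)
  if (smooth && spec$sg_window >= n)
    imugait_stop("filter_error", "smoother window %d >= series length %d",
                 spec$sg_window, n)
  ca <- butter2_lowpass(spec$accel_cutoff, st$fs)
  cg <- butter2_lowpass(spec$gyro_cutoff, st$fs)
  run <- function(x, coef) {
    y <- if (spec$zero_phase) filtfilt2(x, coef) else iir_filter(x, coef$b, coef$a)
    if (smooth) y <- savgol(y, spec$sg_order, spec$sg_window)
    y
  }
  a_f <- apply(a, 2, run, coef = ca)
  om_f <- apply(om, 2, run, coef = cg)
  structure(list(t = st$t, fs = st$fs, a = a_f, omega = om_f,
                 a_dyn = a_d, a_grav = a_g, omega_raw = om,
                 placement = st$placement),
            class = "imu_signal")
}

#' @export
print.imu_signal <- function(x, ...) {
  cat(sprintf("<imu_signal> %d samples @ %.6g Hz; |a| in [%.2f, %.2f] m/s^2, |w| max %.2f rad/s\n",
              length(x$t), x$fs, min(sqrt(rowSums(x$a^2))),
              max(sqrt(rowSums(x$a^2))), max(sqrt(rowSums(x$omega^2)))))
  invisible(x)
}

#' Export an IMU signal as tidy CSV
#'
#' Columns `t, ax, ay, az, gx, gy, gz`; a comment header names units
#' (seconds, m/s^2, rad/s) and the sensor frame.
#'
#' @param imu An `imu_signal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(imu, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# imugait imu_signal export",
               "# t [s]; ax,ay,az [m/s^2]; gx,gy,gz [rad/s]; sensor frame (x normal, y limb axis, z transverse)"),
             con)
  df <- data.frame(t = imu$t,
                   ax = imu$a[, 1], ay = imu$a[, 2], az = imu$a[, 3],
                   gx = imu$omega[, 1], gy = imu$omega[, 2], gz = imu$omega[, 3])
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
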