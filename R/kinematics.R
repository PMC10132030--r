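# Segment pose trajectories: containers, validation, columnar-text I/O and
# uniform resampling.
#
# A segment trajectory is the kinematic substrate of the whole pipeline: a
# time-uniform stream of poses, each a proper rotation matrix Q (GLOBAL ->
# LOCAL, i.e. v_local = Q v_global) and a segment-origin position p in the
# global frame.  Units are seconds and metres; the global frame is
# right-handed with x anterior-posterior, y vertical (gravity-carrying,
# j = (0,1,0)) and z medio-lateral.

SEGMENT_IDS <- as.vector(outer(c("upper_leg", "lower_leg", "shoe"),
                               c("left", "right"), paste, sep = "_"))

#' Construct a segment pose trajectory
#'
#' @param t Numeric vector of timestamps (s), strictly increasing and
#'   uniformly spaced (to 1e-6 s).
#' @param Q `3 x 3 x n` array of rotation matrices mapping global-frame
#'   vectors into the segment-local frame.  Matrices off orthonormality by
#'   less than `tol_fix` are re-projected onto the nearest rotation; worse
#'   violations (or improper matrices, det <= 0) are rejected.
#' @param p `n x 3` matrix of segment-origin positions (m, global frame).
#' @param segment_id One of `"upper_leg"`, `"lower_leg"`, `"shoe"` crossed
#'   with `"_left"`/`"_right"`, or any other identifier for free-form use.
#' @param tol_fix Orthonormality defect above which a matrix is rejected
#'   rather than re-projected.
#' @return An object of class `segment_trajectory` with fields `t`, `Q`,
#'   `p`, `fs`, `segment_id`.
#' @export
#' @examples
#' n <- 11
#' tr <- segment_trajectory(seq(0, 0.1, by = 0.01),
#'                          array(diag(3), c(3, 3, n)),
#'                          matrix(0, n, 3), "lower_leg_left")
#' tr$fs
segment_trajectory <- function(t, Q, p, segment_id = "segment",
                               tol_fix = 1e-4) {
  n <- length(t)
  if (n < 2) imugait_stop("sampling_error", "a trajectory needs at least 2 samples")
  if (!is.array(Q) || !all(dim(Q) == c(3, 3, n)))
    imugait_stop("format_error", "Q must be a 3 x 3 x n array matching length(t) = %d", n)
  p <- as.matrix(p)
  if (!all(dim(p) == c(n, 3)))
    imugait_stop("format_error", "p must be an n x 3 matrix")
  dt <- diff(t)
  if (any(dt <= 0)) imugait_stop("sampling_error", "timestamps must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6)
    imugait_stop("sampling_error", "non-uniform time base (dt spread %.3g s)", max(dt) - min(dt))
  for (i in seq_len(n)) {
    defect <- orthonormality_defect(Q[, , i])
    if (defect > tol_fix)
      imugait_stop("invalid_rotation_error",
                   "sample %d: orthonormality defect %.3g exceeds %.3g", i, defect, tol_fix)
    if (det(Q[, , i]) <= 0)
      imugait_stop("invalid_rotation_error", "sample %d: det(Q) <= 0 (reflection)", i)
    if (defect > 1e-9) Q[, , i] <- nearest_rotation(Q[, , i])
  }
  structure(list(t = as.numeric(t), Q = Q, p = unname(p),
                 fs = 1 / mean(dt), segment_id = segment_id),
            class = "segment_trajectory")
}

#' @export
print.segment_trajectory <- function(x, ...) {
  cat(sprintf("<segment_trajectory> %s: %d samples @ %.6g Hz, t in [%.3f, %.3f] s\n",
              x$segment_id, length(x$t), x$fs, x$t[1], x$t[length(x$t)]))
  invisible(x)
}

#' Vertical ground-reaction-force trace
#'
#' @param t Timestamps (s), uniform.
#' @param f_v Vertical GRF (N), non-negative everywhere (zero during swing).
#' @param side `"left"` or `"right"`.
#' @return An object of class `grf_trace`.
#' @export
grf_trace <- function(t, f_v, side = c("left", "right")) {
  side <- match.arg(side)
  if (length(t) != length(f_v))
    imugait_stop("format_error", "t and f_v lengths differ")
  if (any(f_v < 0))
    imugait_stop("format_error", "vertical GRF must be non-negative")
  dt <- diff(t)
  if (any(dt <= 0) || max(dt) - min(dt) > 1e-6)
    imugait_stop("sampling_error", "GRF time base must be strictly increasing and uniform")
  structure(list(t = as.numeric(t), f_v = as.numeric(f_v), side = side,
                 fs = 1 / mean(dt)),
            class = "grf_trace")
}

# ---------------------------------------------------------------------------
# Canonical columnar dialect: tab-separated, OpenSim-style storage header
# terminated by an `endheader` sentinel, one `time` column, then per-segment
# rotation matrices stored ROW-MAJOR in 9 columns (R11, R12, R13, R21, ...)
# followed by the 3 origin-position columns (px, py, pz).

#' Write a segment trajectory in the canonical columnar dialect
#'
#' @param traj A [segment_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pose_trajectory <- function(traj, path) {
  n <- length(traj$t)
  rows <- t(apply(traj$Q, 3, function(m) as.vector(t(m))))  # row-major
  M <- cbind(traj$t, rows, traj$p)
  cols <- c("time",
            paste0(traj$segment_id, "_R", as.vector(t(outer(1:3, 1:3, paste0)))),
            paste0(traj$segment_id, "_p", c("x", "y", "z")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("%s", traj$segment_id),
               "version=1",
               sprintf("nRows=%d", n),
               sprintf("nColumns=%d", ncol(M)),
               "inDegrees=no",
               sprintf("dataRate=%.17g", traj$fs),
               "endheader",
               paste(cols, collapse = "\t")), con)
  utils::write.table(format(M, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_storage_table <- function(path) {
  if (!file.exists(path)) imugait_stop("format_error", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  eh <- which(trimws(lines) == "endheader")
  if (length(eh) != 1)
    imugait_stop("format_error", "malformed header: missing `endheader` sentinel in %s", path)
  header <- strsplit(trimws(lines[eh + 1]), "\t")[[1]]
  if (length(header) < 2 || header[1] != "time")
    imugait_stop("format_error", "malformed header: first data column must be `time`")
  dat <- utils::read.table(text = lines[(eh + 2):length(lines)], sep = "\t",
                           col.names = header, check.names = FALSE)
  dat
}

#' Load a segment pose trajectory from the canonical columnar dialect
#'
#' Reads the tab-separated storage dialect written by
#' [write_pose_trajectory()]: an `endheader`-terminated header, a `time`
#' column, nine row-major rotation-matrix columns and three position
#' columns.  Near-orthonormal matrices (defect below 1e-4) are
#' re-orthonormalised by projection onto the nearest rotation; worse
#' violations and improper (det <= 0) matrices are rejected.
#'
#' @param path File path.
#' @param segment_id Optional segment identifier; defaults to the common
#'   prefix of the data columns.
#' @return A [segment_trajectory()].
#' @export
load_pose_trajectory <- function(path, segment_id = NULL) {
  dat <- read_storage_table(path)
  header <- names(dat)
  if (ncol(dat) != 13)
    imugait_stop("format_error", "expected 13 columns (time + 9 rotation + 3 position), got %d", ncol(dat))
  if (is.null(segment_id))
    segment_id <- sub("_R11$", "", header[2])
  n <- nrow(dat)
  Q <- array(0, c(3, 3, n))
  R <- as.matrix(dat[, 2:10])
  for (i in seq_len(n)) Q[, , i] <- matrix(R[i, ], 3, 3, byrow = TRUE)
  segment_trajectory(dat$time, Q, as.matrix(dat[, 11:13]), segment_id)
}

#' Write / load a GRF trace in the canonical columnar dialect
#'
#' @param grf A [grf_trace()].
#' @param path File path.
#' @return `write_grf_trace`: `path` invisibly; `load_grf_trace`: a
#'   [grf_trace()].
#' @export
write_grf_trace <- function(grf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("grf_%s", grf$side),
               "version=1",
               sprintf("nRows=%d", length(grf$t)),
               "nColumns=2",
               "inDegrees=no",
               "endheader",
               paste(c("time", sprintf("f_v_%s", grf$side)), collapse = "\t")), con)
  utils::write.table(format(cbind(grf$t, grf$f_v), digits = 17, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_grf_trace
#' @param side Body side; defaults to the side encoded in the force column
#'   name.
#' @export
load_grf_trace <- function(path, side = NULL) {
  dat <- read_storage_table(path)
  if (ncol(dat) != 2)
    imugait_stop("format_error", "expected 2 columns (time, f_v), got %d", ncol(dat))
  if (is.null(side))
    side <- if (grepl("right", names(dat)[2])) "right" else "left"
  grf_trace(dat$time, dat[[2]], side)
}

# ---------------------------------------------------------------------------

#' Resample a trajectory to a uniform target rate
#'
#' Positions are linearly interpolated; rotations are interpolated on the
#' rotation manifold (geodesic interpolation of the relative rotation
#' between bracketing samples), which preserves orthonormality exactly.
#'
#' @param traj A [segment_trajectory()].
#' @param fs_target Target sampling rate (Hz); at most 10x the input rate.
#' @return A [segment_trajectory()] uniform at `fs_target` covering the same
#'   time span (last partial step dropped).
#' @export
resample_uniform <- function(traj, fs_target) {
  if (fs_target <= 0) imugait_stop("sampling_error", "fs_target must be positive")
  if (fs_target > 10 * traj$fs)
    imugait_stop("upsampling_limit_error",
                 "fs_target %.3g exceeds 10x the input rate %.3g", fs_target, traj$fs)
  t_new <- seq(traj$t[1], traj$t[length(traj$t)], by = 1 / fs_target)
  if (isTRUE(all.equal(fs_target, traj$fs, tolerance = 1e-9)) &&
      length(t_new) == length(traj$t))
    return(traj)
  p_new <- apply(traj$p, 2, function(col) stats::approx(traj$t, col, t_new)$y)
  idx <- findInterval(t_new, traj$t, rightmost.closed = TRUE)
  idx[idx >= length(traj$t)] <- length(traj$t) - 1
  Q_new <- array(0, c(3, 3, length(t_new)))
  for (k in seq_along(t_new)) {
    i <- idx[k]
    s <- (t_new[k] - traj$t[i]) / (traj$t[i + 1] - traj$t[i])
    Qa <- traj$Q[, , i]; Qb <- traj$Q[, , i + 1]
    w <- so3_log(Qb %*% t(Qa))
    Q_new[, , k] <- so3_exp(s * w) %*% Qa
  }
  segment_trajectory(t_new, Q_new, p_new, traj$segment_id)
}

#' World trajectory of a rigidly attached sensor
#'
#' Propagates a segment trajectory to a sensor placement attached rigidly
#' (weld) to the segment: the sensor position is
#' `k(t) = p(t) + t(Q(t)) %*% offset_local`, and the sensor orientation is
#' the mount rotation composed with the segment's global->local rotation,
#' `Q_s(t) = M %*% Q(t)`.
#'
#' @param traj A [segment_trajectory()].
#' @param placement A [sensor_placement()] whose `segment_id` matches
#'   `traj$segment_id` up to the side suffix (a placement built for
#'   `"lower_leg"` attaches to `"lower_leg_left"` or `"lower_leg_right"`).
#' @return An object of class `sensor_trajectory` with fields `t`, `k`
#'   (`n x 3` world positions), `Q` (`3 x 3 x n` global->sensor rotations),
#'   `fs`, `placement`.
#' @export
sensor_world_trajectory <- function(traj, placement) {
  base <- sub("_(left|right)$", "", traj$segment_id)
  if (!(placement$segment_id %in% c(traj$segment_id, base)))
    imugait_stop("attachment_error",
                 "placement for segment `%s` cannot attach to trajectory `%s`",
                 placement$segment_id, traj$segment_id)
  n <- length(traj$t)
  k <- matrix(0, n, 3)
  Qs <- array(0, c(3, 3, n))
  M <- placement$mount_rotation
  off <- placement$offset_local
  for (i in seq_len(n)) {
    k[i, ] <- traj$p[i, ] + drop(t(traj$Q[, , i]) %*% off)
    Qs[, , i] <- M %*% traj$Q[, , i]
  }
  structure(list(t = traj$t, k = k, Q = Qs, fs = traj$fs,
                 placement = placement),
            class = "sensor_trajectory")
}

#' @export
print.sensor_trajectory <- function(x, ...) {
  cat(sprintf("<sensor_trajectory> %s R%d/S%d: %d samples @ %.6g Hz\n",
              x$placement$segment_id, x$placement$ring, x$placement$slot,
              length(x$t), x$fs))
  invisible(x)
}
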