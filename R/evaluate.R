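# Reference-event extraction, timing-error metrics, cross-validation
# strategies, rotatory/translatory repositioning decomposition and
# signal-agreement metrics.

#' Extract reference gait events from a vertical GRF trace
#'
#' Stance is the set of samples with force above `floor` (swing is exactly
#' zero in clean data): IC is the first sample of each rising edge out of
#' a zero-force interval, TO the first sample back at the floor, located
#' via the sign structure of the (optionally smoothed) first derivative.
#' MSt/MSw cannot be derived from a vertical GRF alone; supply them from
#' scenario ground truth via `ground_truth` (they are merged into the
#' returned series).
#'
#' @param grf A [grf_trace()].
#' @param floor Force floor (N) separating swing from stance.
#' @param smooth_cutoff Low-pass cut-off (Hz) applied to the derivative
#'   before edge refinement; `NULL` disables smoothing.
#' @param ground_truth Optional list with `MSt` and `MSw` times (s).
#' @return An `event_series` (ICs and TOs interleaved, plus any merged
#'   mid-phase events).
#' @export
extract_reference_events <- function(grf, floor = 0, smooth_cutoff = NULL,
                                     ground_truth = NULL) {
  f <- grf$f_v
  if (!is.null(smooth_cutoff))
    f <- filtfilt2(f, butter2_lowpass(smooth_cutoff, grf$fs))
  up <- f > floor
  if (!any(up)) imugait_stop("no_stance_error", "GRF trace contains no stance phase")
  if (all(up)) return(new_event_series(grf$side, phase_model = 2))
  d <- diff(up)
  ic <- grf$t[which(d == 1) + 1]   # first loaded sample
  to <- grf$t[which(d == -1) + 1]  # first unloaded sample
  kind <- c(rep("IC", length(ic)), rep("TO", length(to)))
  tt <- c(ic, to)
  if (!is.null(ground_truth)) {
    for (k in c("MSt", "MSw")) {
      if (!is.null(ground_truth[[k]])) {
        kind <- c(kind, rep(k, length(ground_truth[[k]])))
        tt <- c(tt, ground_truth[[k]])
      }
    }
  }
  o <- order(tt)
  new_event_series(grf$side, kind[o], tt[o], phase_model = 4)
}

#' Mean stride duration from reference events
#'
#' Mean of successive IC-to-IC intervals of one side.
#'
#' @param ref An `event_series` containing at least two ICs.
#' @return Mean stride duration (s).
#' @export
mean_stride_duration <- function(ref) {
  ic <- ref$events$t[ref$events$kind == "IC"]
  if (length(ic) < 2)
    imugait_stop("insufficient_events_error",
                 "need >= 2 IC events to estimate stride duration, got %d", length(ic))
  mean(diff(sort(ic)))
}

#' Timing error between detected and reference events
#'
#' Each reference event is matched to the nearest detected event of the
#' same kind (reuse permitted), so missing detections inflate the error --
#' possibly beyond 100 % of the stride duration.  `MAE` is the mean
#' absolute difference (s) over all reference events; `nMAE` expresses it
#' as a percentage of the mean reference stride duration.
#'
#' @param detected,reference `event_series` of the same side.
#' @param kind Event kind to evaluate (`"IC"`, `"MSt"`, `"TO"`, `"MSw"`).
#' @param stride_duration Reference mean stride duration `F_bar` (s);
#'   defaults to [mean_stride_duration()] of `reference`.
#' @param window Optional `c(t0, t1)`: only reference events inside are
#'   evaluated (used by the cross-validation test folds).
#' @return List with `MAE` (s), `nMAE` (%), `n_ref`, `n_det`, `undefined`
#'   (TRUE when no event was detected at all; `MAE`/`nMAE` are `NA` then),
#'   and the match table `matches`.
#' @export
timing_error <- function(detected, reference, kind = "IC",
                         stride_duration = NULL, window = NULL) {
  ref_t <- reference$events$t[reference$events$kind == kind]
  det_t <- detected$events$t[detected$events$kind == kind]
  if (!is.null(window)) ref_t <- ref_t[ref_t >= window[1] & ref_t < window[2]]
  if (is.null(stride_duration)) stride_duration <- mean_stride_duration(reference)
  if (length(ref_t) == 0)
    return(list(MAE = NA_real_, nMAE = NA_real_, n_ref = 0L,
                n_det = length(det_t), undefined = TRUE,
                matches = data.frame(t_ref = numeric(0), t_det = numeric(0))))
  if (length(det_t) == 0)
    return(list(MAE = NA_real_, nMAE = NA_real_, n_ref = length(ref_t),
                n_det = 0L, undefined = TRUE,
                matches = data.frame(t_ref = ref_t, t_det = NA_real_)))
  nearest <- vapply(ref_t, function(tr) det_t[which.min(abs(det_t - tr))], 0)
  mae <- mean(abs(ref_t - nearest))
  list(MAE = mae, nMAE = 100 * mae / stride_duration,
       n_ref = length(ref_t), n_det = length(det_t), undefined = FALSE,
       matches = data.frame(t_ref = ref_t, t_det = nearest))
}

# ---------------------------------------------------------------------------
# Simulated dataset container + cross-validation strategies.

#' Build a simulation dataset for cross-validation
#'
#' Generates one scenario per participant (seeds `seed + 0:(n-1)` applied
#' on top of the template), synthesises the IMU signal of every requested
#' placement on both sides, and extracts reference events from the
#' synthetic GRF (mid-phase events taken from scenario ground truth).
#'
#' @param template A [gait_scenario()]; per-participant seeds override its
#'   `seed`.
#' @param placements List of [sensor_placement()]s (leg or shoe).
#' @param n_participants Number of participants.
#' @param spec A [filter_spec()].
#' @return An object of class `gait_dataset`: per participant a list with
#'   `imu` (`placement id -> list(left, right)`), `ref`
#'   (`side -> event_series`), `stride_duration` (`side -> F_bar`) and the
#'   scenario.
#' @export
build_sim_dataset <- function(template, placements, n_participants = 1,
                              spec = filter_spec()) {
  participants <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    sc <- template
    sc$seed <- template$seed + p - 1
    scn <- generate_scenario(sc)
    imu <- list()
    for (pl in placements) {
      id <- placement_id(pl)
      imu[[id]] <- list(left = scenario_imu(scn, pl, "left", spec),
                        right = scenario_imu(scn, pl, "right", spec))
    }
    ref <- list(); fbar <- list()
    for (side in c("left", "right")) {
      ref[[side]] <- extract_reference_events(
        scn$grf[[side]], ground_truth = scn$ground_truth[[side]])
      fbar[[side]] <- mean_stride_duration(ref[[side]])
    }
    participants[[p]] <- list(imu = imu, ref = ref, stride_duration = fbar,
                              scenario = sc,
                              placements = stats::setNames(placements,
                                                           vapply(placements, placement_id, "")))
  }
  structure(list(participants = participants,
                 placement_ids = vapply(placements, placement_id, "")),
            class = "gait_dataset")
}

#' Contiguous stride folds
#'
#' Splits the strides of one side (successive reference IC intervals) into
#' `k` contiguous blocks and returns their time windows, so every stride
#' is tested exactly once and training/testing never split a stride.
#'
#' @param ref Reference `event_series` with the side's ICs.
#' @param k Number of folds.
#' @return List of `k` windows `c(t0, t1)`.
#' @export
stride_folds <- function(ref, k = 5) {
  ic <- sort(ref$events$t[ref$events$kind == "IC"])
  n_strides <- length(ic) - 1
  if (n_strides < k)
    imugait_stop("strategy_error", "%d strides cannot form %d folds", n_strides, k)
  sizes <- rep(n_strides %/% k, k)
  extra <- n_strides %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  lapply(seq_len(k), function(i) c(ic[starts[i]], ic[ends[i] + 1]))
}

complement_windows <- function(windows, drop) {
  Filter(Negate(is.null), lapply(windows, function(w)
    if (identical(w, drop)) NULL else w))
}

train_pair <- function(part, id, side, params, windows, calibrate_sign) {
  ipsi <- part$imu[[id]][[side]]
  contra <- part$imu[[id]][[setdiff(c("left", "right"), side)]]
  train_detection_params(ipsi$a[, 2], ipsi$omega[, 3], ipsi$t, params,
                         a_y_contra = contra$a[, 2],
                         omega_z_contra = contra$omega[, 3],
                         windows = windows, calibrate_sign = calibrate_sign)
}

eval_pair <- function(part, id, algo, params_l, params_r, windows_by_side) {
  det <- run_phase_model(part$imu[[id]]$left, part$imu[[id]]$right, algo,
                         params_l, params_r)
  rows <- NULL
  for (side in c("left", "right")) {
    for (kind in phase_cycle(params_l$phase_model)) {
      te <- timing_error(det[[side]], part$ref[[side]], kind,
                         stride_duration = part$stride_duration[[side]],
                         window = windows_by_side[[side]])
      rows <- rbind(rows, data.frame(
        placement = id, side = side, event = kind,
        MAE_s = te$MAE, nMAE_pct = te$nMAE,
        n_ref = te$n_ref, n_det = te$n_det, undefined = te$undefined))
    }
  }
  rows
}

average_params <- function(plist) {
  # average the numeric thresholds of a list of trained detection_params
  out <- plist[[1]]
  for (nm in names(out$theta_h))
    out$theta_h[[nm]] <- mean(vapply(plist, function(p) p$theta_h[[nm]], 0))
  for (nm in c("grad_tol_contra", "grad_tol_ipsi"))
    if (!is.null(out[[nm]]))
      out[[nm]] <- mean(vapply(plist, function(p) p[[nm]], 0))
  for (nm in c("gyro_sign", "gyro_sign_contra"))
    if (!is.null(out[[nm]])) {
      s <- mean(vapply(plist, function(p) p[[nm]], 0))
      out[[nm]] <- if (s >= 0) 1 else -1   # majority vote
    }
  out
}

#' Cross-validated timing-error evaluation
#'
#' Runs one of the validation strategies over a [build_sim_dataset()]
#' dataset:
#'
#' * `A1` / `A2a`: user-dependent, position-dependent -- thresholds fitted
#'   per participant AND per sensor on k-1 of k contiguous stride blocks,
#'   tested on the held-out block, rotated k times, fold results averaged.
#' * `A2b`: user-independent -- per-sensor thresholds fitted on every
#'   training participant's full trial and averaged; tested on the
#'   held-out participant; rotated over participants.
#' * `A2c`: user-dependent, position-independent -- per-sensor thresholds
#'   fitted per fold as in A2a, then averaged across all sensors of each
#'   segment instance before testing; gyro-sign calibration is disabled
#'   (fixed +1), since a per-sensor sign is itself position-dependent.
#'
#' @param dataset A `gait_dataset`.
#' @param variant `"A1"`, `"A2a"`, `"A2b"` or `"A2c"`.
#' @param phase_model 1, 2 or 4 (A1: 1 only).
#' @param k Folds for the 5-fold strategies.
#' @param params Template [detection_params()] (phase model is overridden).
#' @return A long-format `error_report` data.frame: participant,
#'   placement, segment, ring, slot, side, event, fold, MAE_s, nMAE_pct,
#'   n_ref, n_det, undefined.
#' @export
crossval <- function(dataset, variant = c("A2a", "A1", "A2b", "A2c"),
                     phase_model = 4, k = 5, params = NULL) {
  variant <- match.arg(variant)
  if (is.null(params)) params <- detection_params(phase_model)
  else { params$phase_model <- phase_model
         params$t_w <- c(`1` = 0.6, `2` = 0.3, `4` = 0.15)[[as.character(phase_model)]] }
  algo <- if (variant == "A1") "A1" else "A2"
  if (variant == "A1" && phase_model != 1)
    imugait_stop("unsupported_combination_error", "A1 supports the 1-phase model only")
  parts <- dataset$participants
  ids <- dataset$placement_ids
  rows <- NULL
  add_rows <- function(rows, r, pidx, fold) {
    if (is.null(r)) return(rows)
    r$participant <- pidx; r$fold <- fold
    rbind(rows, r)
  }
  if (variant %in% c("A1", "A2a", "A2c")) {
    for (pidx in seq_along(parts)) {
      part <- parts[[pidx]]
      folds <- lapply(part$ref, stride_folds, k = k)
      for (fold in seq_len(k)) {
        test_w <- lapply(folds, `[[`, fold)
        fitted <- list()
        for (side in c("left", "right")) {
          train_w <- complement_windows(folds[[side]], folds[[side]][[fold]])
          for (id in ids)
            fitted[[side]][[id]] <- train_pair(part, id, side, params, train_w,
                                               calibrate_sign = variant != "A2c")
        }
        if (variant == "A2c") {
          # average thresholds across all sensors of each segment instance
          seg_of <- vapply(ids, function(id) part$placements[[id]]$segment_id, "")
          for (side in c("left", "right")) {
            for (seg in unique(seg_of)) {
              members <- ids[seg_of == seg]
              avg <- average_params(fitted[[side]][members])
              for (id in members) fitted[[side]][[id]] <- avg
            }
          }
        }
        for (id in ids)
          rows <- add_rows(rows, eval_pair(part, id, algo,
                                           fitted$left[[id]], fitted$right[[id]],
                                           test_w), pidx, fold)
      }
    }
  } else {  # A2b: leave-one-participant-out
    if (length(parts) < 2)
      imugait_stop("strategy_error", "A2b needs >= 2 participants")
    for (hold in seq_along(parts)) {
      train_idx <- setdiff(seq_along(parts), hold)
      fitted <- list()
      for (side in c("left", "right")) {
        for (id in ids) {
          plist <- lapply(train_idx, function(pi)
            train_pair(parts[[pi]], id, side, params, NULL, TRUE))
          fitted[[side]][[id]] <- average_params(plist)
        }
      }
      # evaluate the held-out participant on their interior strides (the
      # first and last stride carry filter/detector boundary transients)
      test_w <- lapply(parts[[hold]]$ref, function(ref) {
        ic <- sort(ref$events$t[ref$events$kind == "IC"])
        if (length(ic) >= 4) c(ic[2], ic[length(ic) - 1]) else range(ic)
      })
      for (id in ids)
        rows <- add_rows(rows, eval_pair(parts[[hold]], id, algo,
                                         fitted$left[[id]], fitted$right[[id]],
                                         test_w),
                         hold, hold)
    }
  }
  meta <- do.call(rbind, lapply(rows$placement, function(id) {
    pl <- parts[[1]]$placements[[id]]
    data.frame(segment = pl$segment_id, ring = pl$ring, slot = pl$slot)
  }))
  rows <- cbind(rows, meta)
  rows$variant <- variant
  rows$phase_model <- phase_model
  class(rows) <- c("error_report", class(rows))
  rows
}

#' Rotatory / translatory error decomposition
#'
#' Splits a position-independent (A2c-style) error report into the
#' rotatory component (all slots of ring `ring`, a uniaxial rotation of
#' the sensor around the limb) and the translatory component (slot `slot`
#' across all rings, a uniaxial translation along the limb), summarised by
#' median and IQR of nMAE.  Shoe placements are rejected: their rings are
#' not azimuthally symmetric.
#'
#' @param report An `error_report` over a leg grid.
#' @param ring Reference ring for the rotatory subset.
#' @param slot Reference slot for the translatory subset.
#' @return List with `rotatory` and `translatory`, each holding the nMAE
#'   values plus `median` and `IQR`.
#' @export
rot_trans_errors <- function(report, ring = 1, slot = 1) {
  if (any(grepl("shoe", report$segment)))
    imugait_stop("unsupported_grid_error",
                 "shoe placements are excluded from the rotatory/translatory analysis")
  rot <- report$nMAE_pct[report$ring == ring]
  tra <- report$nMAE_pct[report$slot == slot]
  summ <- function(x) list(nMAE = x,
                           median = stats::median(x, na.rm = TRUE),
                           IQR = stats::IQR(x, na.rm = TRUE))
  list(rotatory = summ(rot), translatory = summ(tra))
}

#' Export an error report as long-format CSV
#'
#' @param report An `error_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_error_report <- function(report, path) {
  cols <- c("participant", "segment", "ring", "slot", "side", "event",
            "variant", "phase_model", "fold", "MAE_s", "nMAE_pct",
            "n_ref", "n_det", "undefined")
  utils::write.csv(as.data.frame(report)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' nMAE boxplot per segment
#'
#' Boxplots of per-sensor nMAE grouped by segment and event kind,
#' whiskers at 1.5 IQR.
#'
#' @param report An `error_report`.
#' @param path Output image path (PNG); `NULL` plots to the active device.
#' @param ylim_max Upper nMAE axis limit (%%).
#' @return `path`, invisibly.
#' @export
plot_error_report <- function(report, path = NULL, ylim_max = 50) {
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 500)
    on.exit(grDevices::dev.off())
  }
  df <- as.data.frame(report)
  df$group <- interaction(df$segment, df$event, drop = TRUE)
  graphics::boxplot(nMAE_pct ~ group, data = df, las = 2,
                    ylim = c(0, ylim_max), ylab = "nMAE [%]",
                    main = sprintf("%s, %d-phase model",
                                   df$variant[1], df$phase_model[1]),
                    cex.axis = 0.7)
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Agreement metrics between measured and synthesised series
#'
#' Per participant: Pearson r between the paired series, median absolute
#' deviation between them (`MAD = median(|x_meas - x_synth|)`; set
#' `centred = TRUE` for the classical centred variant), RMSE, and
#' `nMAD = 100 * MAD / range` where the normaliser is the peak-to-peak
#' range of the measured series.  Correlations are pooled through
#' Fisher's z transform: mean and normal-theory 95 % confidence interval
#' on the z scale, back-transformed.
#'
#' @param pairs List of participants, each `list(measured =, synthesised =)`
#'   numeric vectors of equal length.
#' @param centred Use the centred MAD.
#' @return List with `r_mean`, `r_ci` (length 2), `per_participant_r`,
#'   `MAD`, `RMSE`, `nMAD` (means across participants) and `undefined`
#'   (TRUE when any series was constant, making r undefined).
#' @export
agreement_metrics <- function(pairs, centred = FALSE) {
  rs <- mad <- rmse <- nmad <- numeric(length(pairs))
  undef <- FALSE
  for (i in seq_along(pairs)) {
    xm <- pairs[[i]]$measured; xs <- pairs[[i]]$synthesised
    if (length(xm) != length(xs))
      imugait_stop("alignment_error", "participant %d: series lengths differ", i)
    if (stats::sd(xm) == 0 || stats::sd(xs) == 0) { undef <- TRUE; rs[i] <- NA }
    else rs[i] <- stats::cor(xm, xs)
    d <- xm - xs
    mad[i] <- if (centred) stats::median(abs(d - stats::median(d))) else stats::median(abs(d))
    rmse[i] <- sqrt(mean(d^2))
    rng <- diff(range(xm))
    nmad[i] <- if (rng > 0) 100 * mad[i] / rng else NA_real_
  }
  z <- atanh(pmin(pmax(rs, -1 + 1e-15), 1 - 1e-15))
  zbar <- mean(z, na.rm = TRUE)
  nz <- sum(!is.na(z))
  ci <- if (nz >= 2) zbar + c(-1, 1) * stats::qt(0.975, nz - 1) * stats::sd(z, na.rm = TRUE) / sqrt(nz)
        else c(NA_real_, NA_real_)
  list(r_mean = tanh(zbar), r_ci = tanh(ci), per_participant_r = rs,
       MAD = mean(mad), RMSE = mean(rmse), nMAD = mean(nmad, na.rm = TRUE),
       undefined = undef)
}
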