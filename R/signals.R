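#' Construct a trial recording
#'
#' Container for one sensor placement's raw triaxial time series during a
#' single 15-m run: three acceleration channels (G, axes X caudal-cranial,
#' Y medial-lateral, Z ventral-dorsal), three angular-velocity channels
#' (dps), a quasi-static standing window used for gravity-offset
#' calibration, and the start-to-goal run segment.
#'
#' Windows are 1-based inclusive index pairs `c(first, last)`. The sensor's
#' dynamic range is +/- 8 G and +/- 1000 dps; samples outside it are
#' rejected (saturated samples sit exactly at the bound).
#'
#' @param accel numeric matrix or data.frame, L x 3, acceleration in G.
#' @param gyro numeric matrix or data.frame, L x 3, angular velocity in dps.
#' @param sampling_interval sampling interval in seconds (default 0.02).
#' @param standing_window inclusive index pair of the standing window.
#' @param run_segment inclusive index pair of the run (start to goal).
#' @param dog_id,phenotype,region,month trial metadata.
#' @return an object of class `trial_recording`.
#' @export
trial_recording <- function(accel, gyro, sampling_interval = 0.02,
                            standing_window, run_segment,
                            dog_id = NA_character_,
                            phenotype = c("WT", "DYS"),
                            region = c("thoracic", "lumbar"),
                            month = NA_integer_) {
  phenotype <- match.arg(phenotype)
  region <- match.arg(region)
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  if (ncol(accel) != 3 || ncol(gyro) != 3)
    stop("accel and gyro must each have three channels (X, Y, Z)")
  L <- nrow(accel)
  if (nrow(gyro) != L)
    stop("acceleration and gyro channels must share one length")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0)
    stop("sampling_interval must be positive")
  if (any(abs(accel) > 8))
    stop("acceleration samples outside the +/- 8 G sensor range")
  if (any(abs(gyro) > 1000))
    stop("angular-velocity samples outside the +/- 1000 dps sensor range")
  check_window <- function(w, name) {
    if (length(w) != 2 || any(!is.finite(w)) || w[1] < 1 || w[2] > L || w[1] > w[2])
      stop(sprintf("%s must be an index pair within 1..%d", name, L))
    as.integer(w)
  }
  standing_window <- check_window(standing_window, "standing_window")
  run_segment <- check_window(run_segment, "run_segment")
  if (standing_window[1] <= run_segment[2] && run_segment[1] <= standing_window[2])
    stop("standing_window and run_segment may not overlap")
  colnames(accel) <- c("x", "y", "z")
  colnames(gyro) <- c("x", "y", "z")
  structure(list(
    dog_id = dog_id, phenotype = phenotype, region = region,
    month = as.integer(month), sampling_interval = sampling_interval,
    accel = accel, gyro = gyro,
    standing_window = standing_window, run_segment = run_segment
  ), class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> dog %s (%s), %s region, month %s: %d samples @ %g ms\n",
    x$dog_id, x$phenotype, x$region, x$month, nrow(x$accel),
    x$sampling_interval * 1000))
  sw <- if (is.null(x$standing_window)) "dropped"
        else sprintf("[%d, %d]", x$standing_window[1], x$standing_window[2])
  cat(sprintf("  standing window %s, run segment [%d, %d]\n",
              sw, x$run_segment[1], x$run_segment[2]))
  invisible(x)
}

#' Remove the gravity (DC) offset from the acceleration channels
#'
#' Estimates the constant gravity component of each acceleration channel as
#' its mean over the standing window (dog in quadrupedal stance) and
#' subtracts it from every sample of that channel. Angular-velocity
#' channels are left untouched: only acceleration carries a gravity offset.
#'
#' The calibration protocol samples the standing offset for 10 s; shorter
#' windows (down to `min_window_s`, for trials where only 2-5 s of stance
#' were available) are accepted with a warning.
#'
#' @param trial a [trial_recording].
#' @param min_window_s minimum acceptable standing-window duration in
#'   seconds; shorter windows are rejected as unusable calibration.
#' @return the corrected `trial_recording`; the standing-window mean of
#'   each acceleration channel is 0 to floating precision.
#' @export
remove_gravity_offset <- function(trial, min_window_s = 1) {
  stopifnot(inherits(trial, "trial_recording"))
  w <- trial$standing_window
  idx <- seq.int(w[1], w[2])
  dur <- length(idx) * trial$sampling_interval
  if (length(idx) == 0 || dur < min_window_s)
    stop(sprintf(
      "standing window of %.3g s is unusable for offset calibration (minimum %g s)",
      dur, min_window_s))
  if (dur < 10)
    warning(sprintf("shortened standing window (%.3g s < 10 s) used for offset calibration",
                    dur))
  offset <- colMeans(trial$accel[idx, , drop = FALSE])
  trial$accel <- sweep(trial$accel, 2, offset)
  trial
}

#' Extract the start-to-goal run segment of a trial
#'
#' Restricts all six channels to the run segment (the samples between the
#' start and goal marks of the 15-m run). The returned trial spans only
#' the segment; its run_segment covers the whole retained series and its
#' standing window is dropped (set to the first retained sample is not
#' meaningful, so downstream offset removal must happen first).
#'
#' @param trial a [trial_recording] with its offset already removed.
#' @return the restricted `trial_recording`.
#' @export
segment_run <- function(trial) {
  stopifnot(inherits(trial, "trial_recording"))
  s <- trial$run_segment
  n <- s[2] - s[1] + 1
  if (n < 2) stop("run segment shorter than 2 samples is degenerate")
  idx <- seq.int(s[1], s[2])
  trial$accel <- trial$accel[idx, , drop = FALSE]
  trial$gyro <- trial$gyro[idx, , drop = FALSE]
  trial$run_segment <- c(1L, n)
  trial$standing_window <- NULL
  class(trial) <- c("run_segmented", class(trial))
  trial
}

#' Mean absolute value of a channel
#'
#' The per-trial instantaneous vector of an axis: the arithmetic mean of
#' the absolute sample values (Ax, Ay, Az for acceleration in G; Gx, Gy,
#' Gz for angular velocity in dps).
#'
#' @param channel non-empty numeric vector.
#' @return non-negative scalar.
#' @export
mean_abs <- function(channel) {
  if (length(channel) == 0) stop("channel is empty")
  mean(abs(channel))
}

#' Per-sample acceleration magnitude series
#'
#' AM_k = sqrt(ax_k^2 + ay_k^2 + az_k^2), the Euclidean norm of the three
#' acceleration axes at each sample.
#'
#' @param ax,ay,az equal-length numeric vectors (G).
#' @return non-negative numeric vector; each AM_k >= max(|ax_k|, |ay_k|, |az_k|).
#' @export
am_series <- function(ax, ay, az) {
  n <- length(ax)
  if (n < 1 || length(ay) != n || length(az) != n)
    stop("ax, ay, az must be non-empty and of equal length")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Trial-averaged acceleration magnitude
#'
#' The mean of [am_series] over the trial — the AM outcome.
#'
#' @inheritParams am_series
#' @return non-negative scalar.
#' @export
trial_am <- function(ax, ay, az) {
  mean(am_series(ax, ay, az))
}

#' Per-trial acceleration ratios
#'
#' Per sample, the percentage contribution of each axis to the
#' acceleration magnitude, 100 * |axis_k| / AM_k; each axis's ratio is the
#' mean of its per-sample values over the trial. Samples with AM_k = 0
#' carry no direction and are dropped from the average; their count is
#' attached as attribute `n_dropped`.
#'
#' @inheritParams am_series
#' @return named vector `c(x=, y=, z=)` of means in \[0, 100\], with
#'   attribute `n_dropped`. Per sample the three ratios sum to between 100
#'   and 100 * sqrt(3), hence so do the returned means.
#' @export
acceleration_ratios <- function(ax, ay, az) {
  am <- am_series(ax, ay, az)
  keep <- am > 0
  n_dropped <- sum(!keep)
  if (!any(keep))
    stop("all samples have zero acceleration magnitude: no motion to apportion")
  r <- c(
    x = mean(100 * abs(ax[keep]) / am[keep]),
    y = mean(100 * abs(ay[keep]) / am[keep]),
    z = mean(100 * abs(az[keep]) / am[keep])
  )
  attr(r, "n_dropped") <- n_dropped
  r
}

#' Summarize a processed trial into its per-trial outcomes
#'
#' Computes, on an offset-corrected and run-segmented trial, the eleven
#' per-trial outcomes: mean absolute acceleration vectors Ax, Ay, Az (G),
#' trial-averaged acceleration magnitude AM (G), the three acceleration
#' ratios (%), and mean absolute angular-velocity vectors Gx, Gy, Gz
#' (dps). Counts of ratio samples dropped at AM = 0 and of samples sitting
#' at the sensor saturation bounds (+/- 8 G, +/- 1000 dps) are attached as
#' attributes `n_dropped` and `n_saturated`.
#'
#' @param trial a [trial_recording], already offset-corrected (see
#'   [remove_gravity_offset]) and segmented (see [segment_run]).
#' @return one-row data.frame with the trial metadata and outcomes.
#' @export
summarize_trial <- function(trial) {
  stopifnot(inherits(trial, "trial_recording"))
  a <- trial$accel; g <- trial$gyro
  ratios <- acceleration_ratios(a[, 1], a[, 2], a[, 3])
  out <- data.frame(
    dog_id = trial$dog_id, phenotype = trial$phenotype,
    region = trial$region, month = trial$month,
    Ax = mean_abs(a[, 1]), Ay = mean_abs(a[, 2]), Az = mean_abs(a[, 3]),
    AM = trial_am(a[, 1], a[, 2], a[, 3]),
    Ax_ratio = unname(ratios["x"]), Ay_ratio = unname(ratios["y"]),
    Az_ratio = unname(ratios["z"]),
    Gx = mean_abs(g[, 1]), Gy = mean_abs(g[, 2]), Gz = mean_abs(g[, 3]),
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- attr(ratios, "n_dropped")
  attr(out, "n_saturated") <- sum(abs(a) >= 8) + sum(abs(g) >= 1000)
  out
}

#' Session summary across repeated 15-m passes
#'
#' Each 15-m pass is one trial; a session (one dog, region and month) is
#' summarized as the unweighted mean of its pass summaries.
#'
#' @param summaries data.frame of rows from [summarize_trial] (stacked).
#' @return data.frame with one row per (dog_id, phenotype, region, month).
#' @export
session_summary <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1)
  keys <- c("dog_id", "phenotype", "region", "month")
  vals <- setdiff(names(summaries), keys)
  out <- aggregate(summaries[vals], summaries[keys], mean)
  out <- out[order(out$region, out$dog_id, out$month), , drop = FALSE]
  rownames(out) <- NULL
  out
}
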