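#' Generate a synthetic gait trial
#'
#' Emulates one 15-m run recording: a quasi-static standing window
#' (gravity offset plus sensor noise only) followed by a periodic run
#' segment built, per axis, as a sum of up to three harmonics of the
#' stride frequency with seeded random phases. Samples are clipped at the
#' sensor's dynamic range (+/- 8 G, +/- 1000 dps), emulating saturation.
#' The same arguments and seed always yield a bit-identical recording.
#'
#' @param profile a [gait_profile].
#' @param duration_s total recording duration in seconds (>= 4, so that a
#'   standing window of at least 2 s plus a run segment both fit).
#' @param sampling_interval_ms sampling interval in milliseconds
#'   (default 20).
#' @param seed integer seed.
#' @param standing_s duration of the leading standing window in seconds
#'   (default 10, the calibration protocol's nominal stance).
#' @param dog_id,region,month metadata carried on the recording.
#' @return a [trial_recording] whose standing window covers the static
#'   part and whose run segment covers the rest.
#' @export
generate_gait_trial <- function(profile, duration_s = 14,
                                sampling_interval_ms = 20, seed = 1,
                                standing_s = 10,
                                dog_id = NA_character_,
                                region = c("thoracic", "lumbar"),
                                month = NA_integer_) {
  stopifnot(inherits(profile, "gait_profile"))
  region <- match.arg(region)
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0)
    stop("duration_s must be positive")
  if (!is.numeric(sampling_interval_ms) || length(sampling_interval_ms) != 1 ||
      sampling_interval_ms <= 0)
    stop("sampling_interval_ms must be positive")
  if (!is.numeric(standing_s) || length(standing_s) != 1 || standing_s < 2)
    stop("standing_s must be at least 2 seconds")
  if (duration_s < 4)
    stop("duration_s must be at least 4 seconds")
  if (duration_s <= standing_s + 1)
    stop("duration_s must exceed standing_s by at least 1 second of run")

  dt <- sampling_interval_ms / 1000
  n <- round(duration_s / dt)
  ns <- round(standing_s / dt)
  tt <- (seq_len(n) - 1) * dt
  run <- seq.int(ns + 1, n)
  # relative weights of the three harmonics; sum to 1 so the summed
  # harmonic peak never exceeds the profile amplitude
  w <- c(1, 0.4, 0.2) / 1.6

  with_seed(seed, {
    make_channels <- function(amps, noise_sd, offset) {
      vapply(1:3, function(j) {
        phases <- runif(3, 0, 2 * pi)
        x <- rep(0, n)
        for (h in 1:3) {
          x[run] <- x[run] +
            amps[j] * w[h] * sin(2 * pi * h * profile$stride_frequency * tt[run] +
                                   phases[h])
        }
        x + offset[j] + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
      }, numeric(n))
    }
    accel <- make_channels(profile$axis_amplitudes, profile$noise_sd,
                           profile$gravity_vector)
    # gyro noise scales with the acceleration noise: 0.05 G ~ a few dps
    gyro <- make_channels(profile$gyro_amplitudes, profile$noise_sd * 60,
                          c(0, 0, 0))
    accel <- pmin(pmax(accel, -8), 8)
    gyro <- pmin(pmax(gyro, -1000), 1000)
    trial_recording(accel, gyro, sampling_interval = dt,
                    standing_window = c(1L, ns),
                    run_segment = c(ns + 1L, n),
                    dog_id = dog_id, phenotype = profile$phenotype,
                    region = region, month = month)
  })
}
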