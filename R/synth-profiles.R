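#' Gait waveform profile for the trial generator
#'
#' Describes the periodic running waveform of one phenotype at one age:
#' gait pattern, stride frequency, per-axis acceleration and
#' angular-velocity amplitudes, sensor noise, and the constant gravity
#' offset picked up by the accelerometer. Dystrophic profiles are built
#' with elementwise lower (and, via slower strides, broader) amplitudes
#' than the matched wild-type profile, emulating the waveforms seen in
#' dystrophic dogs.
#'
#' @param phenotype "WT" or "DYS".
#' @param gait_pattern "gallop", "trot" or "walk".
#' @param stride_frequency strides per second, in (0.5, 6).
#' @param axis_amplitudes length-3 non-negative vector, peak dynamic
#'   acceleration per axis (G), order X/Y/Z.
#' @param gyro_amplitudes length-3 non-negative vector, peak angular
#'   velocity per axis (dps).
#' @param noise_sd non-negative sensor noise SD (G).
#' @param gravity_vector length-3 constant offset (G) added to the
#'   acceleration channels; default standing posture (0, 0, 1).
#' @return an object of class `gait_profile`.
#' @export
gait_profile <- function(phenotype = c("WT", "DYS"),
                         gait_pattern = c("gallop", "trot", "walk"),
                         stride_frequency = 3.2,
                         axis_amplitudes = c(1.6, 1.0, 2.2),
                         gyro_amplitudes = c(120, 200, 150),
                         noise_sd = 0.05,
                         gravity_vector = c(0, 0, 1)) {
  phenotype <- match.arg(phenotype)
  gait_pattern <- match.arg(gait_pattern)
  if (!is.numeric(stride_frequency) || length(stride_frequency) != 1 ||
      stride_frequency <= 0.5 || stride_frequency >= 6)
    stop("stride_frequency must lie in (0.5, 6) strides/s")
  chk3 <- function(v, name) {
    if (length(v) != 3 || any(!is.finite(v)) || any(v < 0))
      stop(sprintf("%s must be three non-negative finite values", name))
    as.numeric(v)
  }
  axis_amplitudes <- chk3(axis_amplitudes, "axis_amplitudes")
  gyro_amplitudes <- chk3(gyro_amplitudes, "gyro_amplitudes")
  if (length(noise_sd) != 1 || !is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be a non-negative scalar")
  if (length(gravity_vector) != 3 || any(!is.finite(gravity_vector)))
    stop("gravity_vector must be three finite values")
  structure(list(
    phenotype = phenotype, gait_pattern = gait_pattern,
    stride_frequency = stride_frequency,
    axis_amplitudes = axis_amplitudes, gyro_amplitudes = gyro_amplitudes,
    noise_sd = noise_sd, gravity_vector = as.numeric(gravity_vector)
  ), class = "gait_profile")
}

#' Default phenotype- and age-specific gait profiles
#'
#' Encodes the study-design expectations: wild-type dogs gallop throughout
#' with amplitudes that rise to a peak (around 4 months in the thoracic
#' region, 7-8 months in the lumbar region) and then plateau; dystrophic
#' dogs show elementwise lower amplitudes that attenuate with age, shift
#' from gallop to trot as disease progresses, and stride more slowly
#' (broader waves). The amplitude scales are configurable order-of-
#' magnitude choices within the sensor's +/- 8 G range; the acceleration
#' literature for running dogs does not pin exact per-axis values.
#'
#' @param phenotype "WT" or "DYS".
#' @param month age in months (study window 2-12).
#' @param region "thoracic" or "lumbar" (sets the age of peak amplitude).
#' @param base_amplitudes WT per-axis acceleration amplitudes at peak (G).
#' @param gain multiplier applied to all dynamic amplitudes (per-dog
#'   variation hook; 1 = nominal).
#' @return a [gait_profile].
#' @export
default_gait_profile <- function(phenotype = c("WT", "DYS"), month,
                                 region = c("thoracic", "lumbar"),
                                 base_amplitudes = c(1.6, 1.0, 2.2),
                                 gain = 1) {
  phenotype <- match.arg(phenotype)
  region <- match.arg(region)
  stopifnot(is.numeric(month), length(month) == 1, month >= 1)
  peak <- if (region == "thoracic") 4 else 7.5
  season <- 0.75 + 0.25 * exp(-(month - peak)^2 / 20)
  amp <- base_amplitudes * season * gain
  if (phenotype == "DYS") {
    decline <- max(0.2, 0.65 - 0.035 * (month - 2))
    amp <- amp * decline
    pattern <- if (month <= 6) "gallop" else "trot"
    freq <- if (pattern == "gallop") 2.6 else 2.0
    gyro <- c(120, 200, 150) * season * decline * gain
    noise <- 0.06
  } else {
    pattern <- "gallop"
    freq <- 3.2
    gyro <- c(120, 200, 150) * season * gain
    noise <- 0.05
  }
  gait_profile(phenotype = phenotype, gait_pattern = pattern,
               stride_frequency = freq, axis_amplitudes = amp,
               gyro_amplitudes = gyro, noise_sd = noise)
}
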