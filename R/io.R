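#' Write / read a trial recording as CSV plus a JSON sidecar
#'
#' The CSV holds the six channels with header
#' `time_s,ax_g,ay_g,az_g,gx_dps,gy_dps,gz_dps`; the sidecar (same path
#' with extension `.json`) holds the metadata and the standing-window /
#' run-segment indices.
#'
#' @param trial a [trial_recording].
#' @param path CSV file path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns the reconstructed [trial_recording].
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  n <- nrow(trial$accel)
  df <- data.frame(
    time_s = (seq_len(n) - 1) * trial$sampling_interval,
    ax_g = trial$accel[, 1], ay_g = trial$accel[, 2], az_g = trial$accel[, 3],
    gx_dps = trial$gyro[, 1], gy_dps = trial$gyro[, 2], gz_dps = trial$gyro[, 3]
  )
  write.csv(df, path, row.names = FALSE)
  meta <- list(
    dog_id = trial$dog_id, phenotype = trial$phenotype,
    region = trial$region, month = trial$month,
    sampling_interval = trial$sampling_interval,
    standing_window = trial$standing_window,
    run_segment = trial$run_segment
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  trial_recording(
    accel = as.matrix(df[, c("ax_g", "ay_g", "az_g")]),
    gyro = as.matrix(df[, c("gx_dps", "gy_dps", "gz_dps")]),
    sampling_interval = meta$sampling_interval,
    standing_window = meta$standing_window, run_segment = meta$run_segment,
    dog_id = meta$dog_id, phenotype = meta$phenotype,
    region = meta$region, month = meta$month
  )
}

#' Write / read an outcome panel as CSV
#'
#' Columns `dog_id,phenotype,region,month,outcome,value,covariate`;
#' phenotype/region/outcome are written as NA when the panel does not
#' carry them. True generating parameters travelling with a synthetic
#' panel are written to `params_path` as JSON when requested.
#'
#' @param panel a [gait_panel].
#' @param path CSV file path.
#' @param params_path optional JSON path for the `true_params` attribute.
#' @return `write_panel_csv` returns `path` invisibly; `read_panel_csv`
#'   returns a [gait_panel].
#' @export
write_panel_csv <- function(panel, path, params_path = NULL) {
  stopifnot(inherits(panel, "gait_panel"))
  get_or_na <- function(col) {
    if (col %in% names(panel)) panel[[col]] else NA
  }
  df <- data.frame(
    dog_id = panel$dog_id, phenotype = get_or_na("phenotype"),
    region = get_or_na("region"), month = panel$month,
    outcome = get_or_na("outcome"), value = panel$value,
    covariate = get_or_na("covariate")
  )
  write.csv(df, path, row.names = FALSE)
  tp <- attr(panel, "true_params")
  if (!is.null(params_path) && !is.null(tp))
    jsonlite::write_json(unclass(tp), params_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_panel_csv
#' @param transform observation transform of the panel being read.
#' @param months optional month window (defaults to the data range).
#' @export
read_panel_csv <- function(path, transform = c("log", "logit100"),
                           months = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  keep <- c("dog_id", "phenotype", "region", "month", "outcome", "value",
            "covariate")
  df <- df[, intersect(keep, names(df)), drop = FALSE]
  drop_all_na <- vapply(df, function(col) all(is.na(col)), logical(1))
  df <- df[, !drop_all_na | names(df) %in% c("dog_id", "month", "value"),
           drop = FALSE]
  gait_panel(df, transform = match.arg(transform), months = months)
}
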