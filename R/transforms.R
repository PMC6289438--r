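#' Observation-scale transforms for panel outcomes
#'
#' Outcomes measured on a positive scale (acceleration, angular velocity,
#' activity counts) enter the local-level model through the natural log:
#' z = log(y). Percentages in (0, 100) (acceleration ratios) enter through
#' the logit of r/100: z = log(r / (100 - r)). `inverse_transform` maps
#' back to the natural scale; the logistic branch uses [stats::plogis] for
#' numerical stability at large |z|.
#'
#' @param values numeric vector on the natural scale.
#' @param z numeric vector on the transformed scale.
#' @param transform "log" or "logit100".
#' @return numeric vector.
#' @export
forward_transform <- function(values, transform = c("log", "logit100")) {
  transform <- match.arg(transform)
  if (transform == "log") {
    bad <- which(!is.finite(values) | values <= 0)
    if (length(bad))
      stop(sprintf("log transform requires positive values; offending row(s): %s",
                   paste(bad, collapse = ", ")))
    log(values)
  } else {
    bad <- which(!is.finite(values) | values <= 0 | values >= 100)
    if (length(bad))
      stop(sprintf("logit100 transform requires values in (0, 100); offending row(s): %s",
                   paste(bad, collapse = ", ")))
    log(values / (100 - values))
  }
}

#' @rdname forward_transform
#' @export
inverse_transform <- function(z, transform = c("log", "logit100")) {
  transform <- match.arg(transform)
  if (transform == "log") exp(z) else 100 * plogis(z)
}

#' Construct an unbalanced dog-month outcome panel
#'
#' A longitudinal panel of one outcome: rows (dog_id, month, value) with
#' an optional covariate column, together with the observation transform
#' under which the local-level model is fitted and the contiguous month
#' window over which the latent trend evolves (months without any
#' observation are allowed; the trend still evolves across them).
#'
#' @param data data.frame with columns `dog_id`, `month`, `value` and
#'   optionally `covariate`.
#' @param transform "log" (positive outcomes) or "logit100" (percentages
#'   in (0, 100)).
#' @param months integer vector of contiguous months spanned by the
#'   trend; defaults to `min(data$month):max(data$month)`.
#' @return an object of class `gait_panel` (a data.frame).
#' @export
gait_panel <- function(data, transform = c("log", "logit100"), months = NULL) {
  transform <- match.arg(transform)
  stopifnot(is.data.frame(data))
  need <- c("dog_id", "month", "value")
  if (!all(need %in% names(data)))
    stop("panel data needs columns dog_id, month, value")
  if (nrow(data) < 1) stop("panel needs at least one observation")
  if (is.null(months)) months <- seq.int(min(data$month), max(data$month))
  months <- as.integer(months)
  if (length(months) < 1 || any(diff(months) != 1))
    stop("months must be a contiguous integer range")
  if (!all(data$month %in% months))
    stop("panel rows outside the month window")
  forward_transform(data$value, transform) # validates the value range
  structure(as.data.frame(data), class = c("gait_panel", "data.frame"),
            transform = transform, months = months)
}

#' Apply the panel's observation transform
#'
#' Adds a `z` column holding the transformed values (log or logit of
#' value/100 scaled to percent). The inverse map restores the inputs to
#' floating precision.
#'
#' @param panel a [gait_panel].
#' @return the panel with a `z` column.
#' @export
transform_values <- function(panel) {
  stopifnot(inherits(panel, "gait_panel"))
  panel$z <- forward_transform(panel$value, attr(panel, "transform"))
  panel
}
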