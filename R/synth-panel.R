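#' True generating parameters of a synthetic panel
#'
#' The local-level model that generates a panel on its transformed scale:
#' latent trend m_t following a Gaussian random walk with evolution
#' variance sigma1_sq, observations z_it ~ N(m_t + beta * x_it,
#' sigma0_sq), and the transform (log or logit100) linking z to the
#' natural scale. Stored alongside generated panels so recovery tests can
#' compare posteriors to the truth.
#'
#' @param m numeric vector, one latent-trend value per month of the study
#'   window (transformed scale).
#' @param sigma0_sq positive observation variance.
#' @param sigma1_sq positive evolution variance.
#' @param beta covariate coefficient (0 when no covariate enters).
#' @param transform "log" or "logit100".
#' @return an object of class `true_panel_params`.
#' @export
true_panel_params <- function(m, sigma0_sq, sigma1_sq, beta = 0,
                              transform = c("log", "logit100")) {
  transform <- match.arg(transform)
  stopifnot(is.numeric(m), length(m) >= 1, all(is.finite(m)))
  if (!is.numeric(sigma0_sq) || sigma0_sq <= 0)
    stop("sigma0_sq must be positive")
  if (!is.numeric(sigma1_sq) || sigma1_sq <= 0)
    stop("sigma1_sq must be positive")
  structure(list(m = as.numeric(m), sigma0_sq = sigma0_sq,
                 sigma1_sq = sigma1_sq, beta = beta, transform = transform),
            class = "true_panel_params")
}

#' Simulate a latent random-walk trend
#'
#' Draws m_1 ~ N(m1, sigma1_sq) anchored at `m1`, then
#' m_t ~ N(m_(t-1), sigma1_sq) across the month window.
#'
#' @param months contiguous integer months.
#' @param m1 starting level (transformed scale).
#' @param sigma1_sq positive evolution variance.
#' @param seed integer seed.
#' @return numeric vector named by month.
#' @export
simulate_latent_trend <- function(months, m1, sigma1_sq, seed = 1) {
  stopifnot(length(months) >= 1, all(diff(months) == 1), sigma1_sq > 0)
  with_seed(seed, {
    steps <- rnorm(length(months), 0, sqrt(sigma1_sq))
    setNames(m1 + cumsum(steps), months)
  })
}

#' Generate a longitudinal outcome panel from the local-level model
#'
#' For each non-missing (dog, month) cell, draws a transformed value from
#' N(m_t + beta * x_it, sigma0_sq) and back-transforms it to the natural
#' scale (exp for log; scaled logistic for logit100, so emitted ratios lie
#' strictly inside (0, 100)). Missing cells are absent from the returned
#' table. The true parameters travel with the panel (attribute
#' `true_params`) for recovery tests.
#'
#' @param params a [true_panel_params]; `length(params$m)` must equal
#'   `length(months)`.
#' @param dog_ids character vector of dogs.
#' @param months contiguous integer months (the study window, e.g. 2:12).
#' @param covariate_table optional data.frame (dog_id, month, x) of
#'   covariate values; when supplied, `params$beta` is applied.
#' @param missing optional data.frame (dog_id, month) of cells to drop.
#' @param seed integer seed.
#' @return a [gait_panel] with attribute `true_params`.
#' @export
generate_panel <- function(params, dog_ids, months, covariate_table = NULL,
                           missing = NULL, seed = 1) {
  stopifnot(inherits(params, "true_panel_params"))
  months <- as.integer(months)
  if (any(diff(months) != 1))
    stop("months must be contiguous")
  if (length(params$m) != length(months))
    stop("params$m must have one entry per month")
  grid <- expand.grid(dog_id = dog_ids, month = months,
                      stringsAsFactors = FALSE)
  if (!is.null(missing) && nrow(missing) > 0) {
    drop <- paste(grid$dog_id, grid$month) %in%
      paste(missing$dog_id, missing$month)
    grid <- grid[!drop, , drop = FALSE]
  }
  if (nrow(grid) == 0) stop("no non-missing cells to generate")
  t_idx <- match(grid$month, months)
  x <- rep(0, nrow(grid))
  if (!is.null(covariate_table)) {
    j <- match(paste(grid$dog_id, grid$month),
               paste(covariate_table$dog_id, covariate_table$month))
    if (anyNA(j))
      stop("covariate_table does not cover every non-missing (dog, month) cell")
    x <- covariate_table$x[j]
  }
  z <- with_seed(seed, {
    params$m[t_idx] + params$beta * x +
      rnorm(nrow(grid), 0, sqrt(params$sigma0_sq))
  })
  value <- inverse_transform(z, params$transform)
  if (params$transform == "logit100")
    stopifnot(all(value > 0), all(value < 100))
  else
    stopifnot(all(value > 0))
  out <- data.frame(dog_id = grid$dog_id, month = grid$month, value = value,
                    stringsAsFactors = FALSE)
  if (!is.null(covariate_table)) out$covariate <- x
  out <- out[order(out$dog_id, out$month), , drop = FALSE]
  rownames(out) <- NULL
  panel <- gait_panel(out, transform = params$transform, months = months)
  attr(panel, "true_params") <- params
  panel
}
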