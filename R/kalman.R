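# Aggregate per-observation data to per-month sufficient statistics for a
# scalar-state local level model: with n_t conditionally independent
# observations of m_t (offsets beta*x subtracted), the stack is equivalent
# to one observation of the month mean with variance sigma0_sq / n_t.
month_stats <- function(z, month, months, beta = 0, x = NULL) {
  if (is.null(x)) x <- rep(0, length(z))
  stopifnot(length(z) == length(month), length(x) == length(z))
  t_idx <- match(month, months)
  if (anyNA(t_idx)) stop("observation months outside the month window")
  TT <- length(months)
  nt <- tabulate(t_idx, TT)
  adj <- z - beta * x
  zbar <- rep(NA_real_, TT)
  s <- vapply(split(adj, factor(t_idx, levels = seq_len(TT))), sum, numeric(1))
  zbar[nt > 0] <- s[nt > 0] / nt[nt > 0]
  list(nt = nt, zbar = zbar, t_idx = t_idx, TT = TT)
}

# Forward Kalman filter for the local level model. Returns filtered means
# and variances plus one-step predictive means/variances per month.
ll_filter <- function(nt, zbar, sigma0_sq, sigma1_sq, m1_prior) {
  TT <- length(nt)
  fm <- fP <- pm <- pP <- numeric(TT)
  a <- m1_prior[1]; P <- m1_prior[2]
  for (t in seq_len(TT)) {
    if (t > 1) P <- P + sigma1_sq
    pm[t] <- a; pP[t] <- P
    if (nt[t] > 0) {
      R <- sigma0_sq / nt[t]
      K <- P / (P + R)
      a <- a + K * (zbar[t] - a)
      P <- (1 - K) * P
    }
    fm[t] <- a; fP[t] <- P
  }
  list(fm = fm, fP = fP, pm = pm, pP = pP)
}

#' Exact Kalman smoother for the local-level model
#'
#' Computes the exact Gaussian smoothed marginals of the latent trend m_t
#' in the model z_it ~ N(m_t + beta * x_it, sigma0_sq),
#' m_t ~ N(m_(t-1), sigma1_sq), with prior
#' m_1 ~ N(m1_prior\[1\], m1_prior\[2\]), via forward filtering and the
#' Rauch-Tung-Striebel backward recursion. Multiple observations within a
#' month enter as conditionally independent measurements of the scalar
#' state; months without observations get pure prediction/smoothing
#' updates. Serves as the exact-inference oracle for the MCMC fitter.
#'
#' @param z numeric vector of transformed observations.
#' @param month integer vector, the month of each observation.
#' @param sigma0_sq,sigma1_sq positive observation and evolution variances.
#' @param beta covariate coefficient (default 0).
#' @param x optional covariate vector matching `z`.
#' @param months contiguous month window (default `min(month):max(month)`).
#' @param m1_prior length-2 vector `c(mean, variance)` of the prior on
#'   m_1 (default N(0, 100)).
#' @return data.frame (month, mean, var, n_obs) of smoothed marginals.
#' @export
kalman_smoother <- function(z, month, sigma0_sq, sigma1_sq, beta = 0,
                            x = NULL, months = NULL,
                            m1_prior = c(0, 100)) {
  if (!is.numeric(sigma0_sq) || sigma0_sq <= 0)
    stop("sigma0_sq must be positive")
  if (!is.numeric(sigma1_sq) || sigma1_sq <= 0)
    stop("sigma1_sq must be positive")
  if (is.null(months)) months <- seq.int(min(month), max(month))
  if (any(diff(months) != 1)) stop("months must be contiguous")
  ms <- month_stats(z, month, months, beta, x)
  f <- ll_filter(ms$nt, ms$zbar, sigma0_sq, sigma1_sq, m1_prior)
  TT <- ms$TT
  sm <- f$fm; sP <- f$fP
  if (TT > 1) {
    for (t in seq.int(TT - 1, 1)) {
      C <- f$fP[t] / f$pP[t + 1] # P_{t|t} / P_{t+1|t}
      sm[t] <- f$fm[t] + C * (sm[t + 1] - f$pm[t + 1])
      sP[t] <- f$fP[t] + C^2 * (sP[t + 1] - f$pP[t + 1])
    }
  }
  data.frame(month = months, mean = sm, var = sP, n_obs = ms$nt)
}

# One forward-filtering backward-sampling draw of m_1..m_T given the
# variances (and covariate offsets already folded into zbar).
ffbs_draw <- function(nt, zbar, sigma0_sq, sigma1_sq, m1_prior) {
  f <- ll_filter(nt, zbar, sigma0_sq, sigma1_sq, m1_prior)
  TT <- length(nt)
  m <- numeric(TT)
  m[TT] <- rnorm(1, f$fm[TT], sqrt(f$fP[TT]))
  if (TT > 1) {
    for (t in seq.int(TT - 1, 1)) {
      g <- f$fP[t] / (f$fP[t] + sigma1_sq)
      m[t] <- rnorm(1, f$fm[t] + g * (m[t + 1] - f$fm[t]),
                    sqrt(f$fP[t] * sigma1_sq / (f$fP[t] + sigma1_sq)))
    }
  }
  m
}
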