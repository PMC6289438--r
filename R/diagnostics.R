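#' Split-chain convergence statistic
#'
#' Potential scale reduction factor computed after splitting each chain
#' in half (so within-chain drift registers as apparent non-convergence).
#' Values near 1 indicate convergence; fits flag any parameter above the
#' acceptance threshold (default 1.05) in their diagnostics.
#'
#' @param draws numeric matrix, iterations x chains.
#' @return scalar statistic (NA when the draws are essentially constant).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  N <- nrow(draws)
  if (N < 4) return(NA_real_)
  half <- floor(N / 2)
  splits <- do.call(cbind, lapply(seq_len(ncol(draws)), function(c) {
    cbind(draws[seq_len(half), c], draws[seq.int(N - half + 1, N), c])
  }))
  M <- ncol(splits); n <- nrow(splits)
  mu <- colMeans(splits)
  s2 <- apply(splits, 2, var)
  W <- mean(s2)
  B <- n * var(mu)
  if (!is.finite(W) || W <= 1e-300) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-based estimate: total draws divided by the integrated
#' autocorrelation time, using within-chain autocorrelations averaged
#' across chains and Geyer's initial-positive-sequence truncation.
#'
#' @param draws numeric matrix, iterations x chains.
#' @return estimated effective sample size.
#' @export
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  N <- nrow(draws); C <- ncol(draws)
  total <- N * C
  if (N < 4) return(total)
  vars <- apply(draws, 2, var)
  if (all(!is.finite(vars)) || all(vars <= 1e-300)) return(total)
  lag_max <- min(N - 1, 200)
  rho <- rowMeans(vapply(seq_len(C), function(c) {
    if (vars[c] <= 1e-300) rep(0, lag_max + 1)
    else drop(acf(draws[, c], lag.max = lag_max, plot = FALSE,
                  demean = TRUE)$acf)
  }, numeric(lag_max + 1)))
  # Geyer initial positive sequence on paired autocorrelations
  tau <- 1
  k <- 1
  while (k + 1 <= lag_max) {
    pair <- rho[k + 1] + rho[k + 2]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  max(1, min(total, total / tau))
}
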