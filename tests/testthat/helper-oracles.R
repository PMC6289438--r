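# Independent oracles used across the suite. These deliberately avoid the
# package's own recursions: the smoother oracle conditions the dense joint
# Gaussian directly, and the rank-test oracle enumerates group assignments
# by bitmask.

# Exact smoothed marginals of the local level model by conditioning the
# joint (m_1..m_T, z_1..z_n) Gaussian. Prior: m_1 ~ N(m1_mean, m1_var),
# m_t = m_{t-1} + eta_t.
dense_smoother_oracle <- function(z, month, sigma0_sq, sigma1_sq, beta = 0,
                                  x = NULL, months = NULL,
                                  m1_prior = c(0, 100)) {
  if (is.null(months)) months <- seq.int(min(month), max(month))
  if (is.null(x)) x <- rep(0, length(z))
  TT <- length(months)
  t_idx <- match(month, months)
  Smm <- outer(seq_len(TT), seq_len(TT),
               function(s, t) m1_prior[2] + (pmin(s, t) - 1) * sigma1_sq)
  Smz <- Smm[, t_idx, drop = FALSE]
  Szz <- Smm[t_idx, t_idx, drop = FALSE] + diag(sigma0_sq, length(z))
  mu_m <- rep(m1_prior[1], TT)
  resid <- z - beta * x - m1_prior[1]
  K <- Smz %*% solve(Szz)
  mean <- mu_m + drop(K %*% resid)
  var <- diag(Smm - K %*% t(Smz))
  data.frame(month = months, mean = mean, var = var)
}

# Exact two-sided Mann-Whitney p by bitmask enumeration of all
# assignments of the pooled midranks to group A.
mw_exact_oracle <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  mu <- n1 * (length(b)) / 2
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- abs(u_of(seq_len(n1)) - mu)
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(bits) != n1) next
    total <- total + 1L
    if (abs(u_of(bits) - mu) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# Toy trial with fully controlled channels (no generator involvement).
make_toy_trial <- function(accel, gyro = NULL, dt = 0.02,
                           standing = NULL, run = NULL, ...) {
  accel <- as.matrix(accel)
  if (is.null(gyro)) gyro <- matrix(0, nrow(accel), 3)
  L <- nrow(accel)
  if (is.null(standing)) standing <- c(1, max(1, floor(L / 4)))
  if (is.null(run)) run <- c(standing[2] + 1, L)
  trial_recording(accel, gyro, sampling_interval = dt,
                  standing_window = standing, run_segment = run, ...)
}

# Small simulated covariate panel at the study scale, returning the panel
# and its truth; shared by recovery tests.
make_recovery_panel <- function(beta, seed, n_dogs = 6, months = 2:12,
                                sigma0_sq = 0.04, sigma1_sq = 0.01) {
  dogs <- sprintf("d%02d", seq_len(n_dogs))
  cov <- generate_covariate_series("clinical_score", dogs, months,
                                   severity = 0.8,
                                   seed = derive_seed(seed, "cov"))
  cov <- standardize_covariate(cov)
  m <- simulate_latent_trend(months, m1 = 0.4, sigma1_sq = sigma1_sq,
                             seed = derive_seed(seed, "m"))
  params <- true_panel_params(m, sigma0_sq, sigma1_sq, beta = beta,
                              transform = "log")
  generate_panel(params, dogs, months,
                 covariate_table = cov[c("dog_id", "month", "x")],
                 seed = derive_seed(seed, "panel"))
}
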