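#' MCMC settings for the local-level sampler
#'
#' @param chains number of independent chains.
#' @param iterations iterations per chain (including burn-in).
#' @param burn_in iterations discarded per chain.
#' @param thin keep every `thin`-th retained draw.
#' @param seed integer base seed; each chain derives its own stream.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, iterations = 10000, burn_in = 5000,
                         thin = 1, seed = 1) {
  stopifnot(chains >= 1, iterations > burn_in, burn_in >= 0, thin >= 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)), class = "mcmc_control")
}

#' Prior specification for the local-level model
#'
#' Defaults are weakly informative on the transformed scale: diffuse
#' normal on the initial level and on the covariate coefficient, vague
#' conjugate inverse-gamma on both variances.
#'
#' @param m1_mean,m1_var prior N(m1_mean, m1_var) on the initial level.
#' @param sigma0_shape,sigma0_rate inverse-gamma prior on the observation
#'   variance sigma0^2.
#' @param sigma1_shape,sigma1_rate inverse-gamma prior on the evolution
#'   variance sigma1^2.
#' @param beta_mean,beta_var prior N(beta_mean, beta_var) on beta.
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(m1_mean = 0, m1_var = 100,
                       sigma0_shape = 0.001, sigma0_rate = 0.001,
                       sigma1_shape = 0.001, sigma1_rate = 0.001,
                       beta_mean = 0, beta_var = 100) {
  stopifnot(m1_var > 0, sigma0_shape > 0, sigma0_rate > 0,
            sigma1_shape > 0, sigma1_rate > 0, beta_var > 0)
  structure(list(m1_mean = m1_mean, m1_var = m1_var,
                 sigma0_shape = sigma0_shape, sigma0_rate = sigma0_rate,
                 sigma1_shape = sigma1_shape, sigma1_rate = sigma1_rate,
                 beta_mean = beta_mean, beta_var = beta_var),
            class = "prior_spec")
}

#' Fit the Bayesian local-level model to a dog-month panel
#'
#' Fits, by Gibbs sampling, the state-space model
#' z_it ~ N(m_t + beta * x_it, sigma0^2), m_t ~ N(m_(t-1), sigma1^2),
#' where z is the panel's transformed outcome (log or logit100), m_t the
#' shared latent trend of the group (no subject-level term — all dogs in
#' a group share one trend), and beta the coefficient of an optional
#' covariate. The sampler alternates (a) a joint forward-filtering
#' backward-sampling draw of m_1..m_T, (b) conjugate inverse-gamma draws
#' of both variances, (c) a conjugate normal draw of beta. Reruns with
#' the same seed give identical draws.
#'
#' @param panel a [gait_panel]; a `covariate` column, if present and
#'   complete, activates the beta term (otherwise beta is fixed at 0 and
#'   omitted from the fit).
#' @param mcmc an [mcmc_control].
#' @param priors a [prior_spec].
#' @param fixed optional named list fixing `sigma0_sq`, `sigma1_sq`
#'   and/or `beta` at point values instead of sampling them (degenerate
#'   point priors; used e.g. to validate the sampler against the exact
#'   smoother).
#' @param standardize_covariate standardize the covariate to mean 0,
#'   SD 1 before fitting (default FALSE: raw scale).
#' @param rhat_threshold convergence is flagged (not an error) when any
#'   parameter's split-chain statistic exceeds this (default 1.05).
#' @return an object of class `local_level_fit`: per-month posterior
#'   trend summaries on the transformed and natural scales, variance and
#'   beta summaries (with `excludes_zero` per the 95% credible-interval
#'   decision rule), retained draws, and per-parameter effective sample
#'   size and split-chain convergence diagnostics.
#' @export
fit_local_level <- function(panel, mcmc = mcmc_control(),
                            priors = prior_spec(), fixed = list(),
                            standardize_covariate = FALSE,
                            rhat_threshold = 1.05) {
  stopifnot(inherits(panel, "gait_panel"), inherits(mcmc, "mcmc_control"),
            inherits(priors, "prior_spec"))
  panel <- transform_values(panel)
  months <- attr(panel, "months")
  transform <- attr(panel, "transform")
  if (length(unique(panel$month)) < 2)
    stop("fewer than 2 months with data: the trend is not identifiable")
  has_cov <- "covariate" %in% names(panel) && !all(is.na(panel$covariate))
  if (has_cov && anyNA(panel$covariate))
    stop("covariate column is incomplete")
  x <- if (has_cov) panel$covariate else NULL
  if (has_cov && standardize_covariate) {
    s <- sd(x)
    if (s == 0) stop("covariate has zero variance")
    x <- (x - mean(x)) / s
  }
  z <- panel$z
  n <- length(z)
  TT <- length(months)
  t_idx <- match(panel$month, months)
  m1p <- c(priors$m1_mean, priors$m1_var)

  fix_s0 <- !is.null(fixed$sigma0_sq)
  fix_s1 <- !is.null(fixed$sigma1_sq)
  fix_b <- !is.null(fixed$beta)
  n_keep <- floor((mcmc$iterations - mcmc$burn_in) / mcmc$thin)

  run_chain <- function(chain) {
    with_seed(derive_seed(mcmc$seed, "chain", chain), {
      # initial values: month means (gaps filled with the grand mean)
      zm <- tapply(z, factor(t_idx, levels = seq_len(TT)), mean)
      m <- ifelse(is.na(zm), mean(z), zm)
      s0 <- if (fix_s0) fixed$sigma0_sq else max(var(z) / 2, 1e-4)
      s1 <- if (fix_s1) fixed$sigma1_sq else max(var(z) / 4, 1e-4)
      b <- if (fix_b) fixed$beta else 0
      draws_m <- matrix(NA_real_, n_keep, TT)
      draws <- matrix(NA_real_, n_keep, 3,
                      dimnames = list(NULL, c("sigma0_sq", "sigma1_sq", "beta")))
      k <- 0
      for (it in seq_len(mcmc$iterations)) {
        off <- if (has_cov) b * x else 0
        adj <- z - off
        nt <- tabulate(t_idx, TT)
        s <- vapply(split(adj, factor(t_idx, levels = seq_len(TT))), sum,
                    numeric(1))
        zbar <- ifelse(nt > 0, s / pmax(nt, 1), NA_real_)
        m <- ffbs_draw(nt, zbar, s0, s1, m1p)
        resid <- adj - m[t_idx]
        if (!fix_s0)
          s0 <- 1 / rgamma(1, priors$sigma0_shape + n / 2,
                           priors$sigma0_rate + sum(resid^2) / 2)
        if (!fix_s1 && TT > 1)
          s1 <- 1 / rgamma(1, priors$sigma1_shape + (TT - 1) / 2,
                           priors$sigma1_rate + sum(diff(m)^2) / 2)
        if (has_cov && !fix_b) {
          r <- z - m[t_idx]
          prec <- 1 / priors$beta_var + sum(x^2) / s0
          mu <- (priors$beta_mean / priors$beta_var + sum(x * r) / s0) / prec
          b <- rnorm(1, mu, sqrt(1 / prec))
        }
        if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0) {
          k <- k + 1
          draws_m[k, ] <- m
          draws[k, ] <- c(s0, s1, b)
        }
      }
      list(m = draws_m, pars = draws)
    })
  }

  chains <- lapply(seq_len(mcmc$chains), run_chain)
  m_draws <- do.call(rbind, lapply(chains, `[[`, "m"))
  par_draws <- do.call(rbind, lapply(chains, `[[`, "pars"))
  colnames(m_draws) <- paste0("m_", months)

  qs <- function(v) c(mean = mean(v), lo = unname(quantile(v, 0.025)),
                      hi = unname(quantile(v, 0.975)))
  trend_q <- t(apply(m_draws, 2, qs))
  trend <- data.frame(
    month = months,
    mean = trend_q[, "mean"], lo = trend_q[, "lo"], hi = trend_q[, "hi"],
    natural_mean = inverse_transform(trend_q[, "mean"], transform),
    natural_lo = inverse_transform(trend_q[, "lo"], transform),
    natural_hi = inverse_transform(trend_q[, "hi"], transform),
    row.names = NULL
  )

  # diagnostics over the monitored parameters, per chain
  monitored <- c(colnames(m_draws),
                 "sigma0_sq"[!fix_s0], "sigma1_sq"[!fix_s1],
                 "beta"[has_cov && !fix_b])
  chain_mat <- function(name) {
    sapply(chains, function(ch) {
      if (name %in% colnames(ch$pars)) ch$pars[, name]
      else ch$m[, match(name, colnames(m_draws))]
    })
  }
  diagnostics <- do.call(rbind, lapply(monitored, function(p) {
    mat <- chain_mat(p)
    data.frame(parameter = p, ess = ess_basic(mat), rhat = split_rhat(mat),
               stringsAsFactors = FALSE)
  }))
  rownames(diagnostics) <- NULL
  converged <- all(is.na(diagnostics$rhat) | diagnostics$rhat < rhat_threshold)

  beta_summary <- NULL
  if (has_cov) {
    bq <- qs(par_draws[, "beta"])
    beta_summary <- list(mean = unname(bq["mean"]), lo = unname(bq["lo"]),
                         hi = unname(bq["hi"]),
                         excludes_zero = bq["lo"] > 0 || bq["hi"] < 0)
  }
  structure(list(
    trend = trend,
    sigma0_sq = as.list(qs(par_draws[, "sigma0_sq"])),
    sigma1_sq = as.list(qs(par_draws[, "sigma1_sq"])),
    beta = beta_summary,
    draws = list(m = m_draws, pars = par_draws),
    diagnostics = diagnostics, converged = converged,
    transform = transform, months = months,
    n_obs = n, mcmc = mcmc, priors = priors, fixed = fixed
  ), class = "local_level_fit")
}

#' @export
print.local_level_fit <- function(x, ...) {
  cat(sprintf("<local_level_fit> %d obs over months %d-%d (%s transform)\n",
              x$n_obs, min(x$months), max(x$months), x$transform))
  cat(sprintf("  sigma0^2 %.4g [%.4g, %.4g]; sigma1^2 %.4g [%.4g, %.4g]\n",
              x$sigma0_sq$mean, x$sigma0_sq$lo, x$sigma0_sq$hi,
              x$sigma1_sq$mean, x$sigma1_sq$lo, x$sigma1_sq$hi))
  if (!is.null(x$beta))
    cat(sprintf("  beta %.4g [%.4g, %.4g]%s\n", x$beta$mean, x$beta$lo,
                x$beta$hi,
                if (x$beta$excludes_zero) " (credible interval excludes 0)" else ""))
  if (!x$converged) cat("  WARNING: convergence flagged (split-chain statistic)\n")
  invisible(x)
}

#' Report the covariate coefficient of a fit
#'
#' Point estimate (posterior mean), equal-tailed 95% credible interval
#' (2.5%/97.5% sample quantiles of the draws), and the decision flag
#' `excludes_zero`, true iff 0 lies outside the interval.
#'
#' @param fit a [local_level_fit] fitted with a covariate.
#' @return list (estimate, lower, upper, excludes_zero).
#' @export
coefficient_report <- function(fit) {
  stopifnot(inherits(fit, "local_level_fit"))
  if (is.null(fit$beta))
    stop("fit has no covariate coefficient")
  list(estimate = fit$beta$mean, lower = fit$beta$lo, upper = fit$beta$hi,
       excludes_zero = unname(fit$beta$excludes_zero))
}

#' Compare posterior trends of two groups month by month
#'
#' For two fits over the same months and transform (e.g. wild-type vs
#' dystrophic), reports both natural-scale trend means and 95% bands per
#' month, whether the bands are disjoint, and the signed gap between
#' them (positive when the first group's band lies above the second's).
#'
#' @param fit_a,fit_b [local_level_fit] objects on the same months and
#'   transform.
#' @return data.frame with one row per month.
#' @export
compare_trends <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "local_level_fit"),
            inherits(fit_b, "local_level_fit"))
  if (!identical(fit_a$months, fit_b$months))
    stop("fits cover different month ranges")
  if (!identical(fit_a$transform, fit_b$transform))
    stop("fits use different transforms")
  a <- fit_a$trend; b <- fit_b$trend
  disjoint <- a$natural_lo > b$natural_hi | b$natural_lo > a$natural_hi
  gap <- ifelse(a$natural_lo > b$natural_hi, a$natural_lo - b$natural_hi,
                ifelse(b$natural_lo > a$natural_hi,
                       -(b$natural_lo - a$natural_hi), 0))
  data.frame(
    month = a$month,
    mean_a = a$natural_mean, lo_a = a$natural_lo, hi_a = a$natural_hi,
    mean_b = b$natural_mean, lo_b = b$natural_lo, hi_b = b$natural_hi,
    disjoint = disjoint, gap = gap
  )
}
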