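small_mcmc <- function(seed = 1, iterations = 1500, burn_in = 700,
                       chains = 2) {
  mcmc_control(chains = chains, iterations = iterations, burn_in = burn_in,
               seed = seed)
}

test_that("sampling is deterministic given the seed", {
  pan <- make_recovery_panel(beta = -0.5, seed = 5)
  a <- fit_local_level(pan, mcmc = small_mcmc(3))
  b <- fit_local_level(pan, mcmc = small_mcmc(3))
  expect_identical(a$draws, b$draws)
  c <- fit_local_level(pan, mcmc = small_mcmc(4))
  expect_false(identical(a$draws$pars, c$draws$pars))
})

test_that("with variances and beta fixed, posterior trend means match the exact smoother", {
  pan <- make_recovery_panel(beta = -0.5, seed = 11)
  fit <- fit_local_level(pan, mcmc = small_mcmc(7, iterations = 3000,
                                                burn_in = 1000),
                         fixed = list(sigma0_sq = 0.04, sigma1_sq = 0.01,
                                      beta = -0.5))
  pt <- transform_values(pan)
  sm <- kalman_smoother(pt$z, pt$month, 0.04, 0.01, beta = -0.5,
                        x = pt$covariate, months = attr(pan, "months"))
  for (t in seq_along(sm$month)) {
    draws <- fit$draws$m[, t]
    mcse <- sd(draws) / sqrt(fit$diagnostics$ess[t])
    expect_lt(abs(mean(draws) - sm$mean[t]), 3 * mcse)
    expect_lt(abs(var(draws) - sm$var[t]) / sm$var[t], 0.15)
  }
})

test_that("a constant panel yields a flat trend at the constant", {
  df <- expand.grid(dog_id = c("a", "b", "c"), month = 1:6,
                    stringsAsFactors = FALSE)
  df$value <- 5
  pan <- gait_panel(df, "log")
  fit <- fit_local_level(pan, mcmc = small_mcmc(2))
  expect_true(all(abs(fit$trend$mean - log(5)) < 0.05))
  expect_lt(fit$sigma0_sq$mean, 0.01) # concentrates near its prior floor
})

test_that("quantile ordering and natural-scale bands hold in every fit", {
  pan <- make_recovery_panel(beta = 0, seed = 17)
  fit <- fit_local_level(pan, mcmc = small_mcmc(9))
  with(fit$trend, {
    expect_true(all(lo <= mean & mean <= hi))
    expect_true(all(natural_lo <= natural_mean & natural_mean <= natural_hi))
  })
  expect_gt(fit$sigma0_sq$mean, 0)
  expect_gt(fit$sigma1_sq$mean, 0)
})

test_that("coefficient report follows the 95% credible-interval decision rule", {
  pan <- make_recovery_panel(beta = -0.5, seed = 23)
  fit <- fit_local_level(pan, mcmc = small_mcmc(5))
  rep <- coefficient_report(fit)
  expect_lt(rep$lower, rep$estimate)
  expect_gt(rep$upper, rep$estimate)
  expect_identical(rep$excludes_zero, rep$lower > 0 || rep$upper < 0)

  # degenerate and shifted-normal draw sets exercise the rule directly
  fit2 <- fit
  fit2$beta <- list(mean = 1.3, lo = 1.3, hi = 1.3, excludes_zero = TRUE)
  expect_true(coefficient_report(fit2)$excludes_zero)
  set.seed(1)
  d <- rnorm(10000) + 3
  qs <- unname(quantile(d, c(0.025, 0.975)))
  expect_equal(qs[1], 3 + qnorm(0.025), tolerance = 0.1)
  expect_equal(qs[2], 3 + qnorm(0.975), tolerance = 0.1)
  fit2$beta <- list(mean = mean(d), lo = qs[1], hi = qs[2],
                    excludes_zero = qs[1] > 0 || qs[2] < 0)
  expect_true(coefficient_report(fit2)$excludes_zero)
  d0 <- rnorm(10000) # symmetric around 0
  q0 <- unname(quantile(d0, c(0.025, 0.975)))
  expect_false(q0[1] > 0 || q0[2] < 0)

  fit_nocov <- fit_local_level(
    gait_panel(as.data.frame(pan)[c("dog_id", "month", "value")], "log"),
    mcmc = small_mcmc(5))
  expect_null(fit_nocov$beta)
  expect_error(coefficient_report(fit_nocov), "no covariate")
})

test_that("fitting logit100 data equals fitting the log model on matched z", {
  set.seed(33)
  months <- 1:6
  dogs <- c("a", "b", "c")
  grid <- expand.grid(dog_id = dogs, month = months,
                      stringsAsFactors = FALSE)
  z <- rnorm(nrow(grid), 0.3, 0.4)
  log_pan <- gait_panel(transform(grid, value = exp(z)), "log")
  logit_pan <- gait_panel(transform(grid, value = 100 * plogis(z)),
                          "logit100")
  fa <- fit_local_level(log_pan, mcmc = small_mcmc(6))
  fb <- fit_local_level(logit_pan, mcmc = small_mcmc(6))
  expect_equal(fa$trend$mean, fb$trend$mean, tolerance = 1e-8)
  expect_equal(fa$draws$pars, fb$draws$pars, tolerance = 1e-8)
})

test_that("the excludes-zero decision on a strong effect survives a prior change", {
  pan <- make_recovery_panel(beta = -0.8, seed = 41)
  f1 <- fit_local_level(pan, mcmc = small_mcmc(8))
  f2 <- fit_local_level(pan, mcmc = small_mcmc(8),
                        priors = prior_spec(beta_var = 1,
                                            sigma0_shape = 0.01,
                                            sigma0_rate = 0.01,
                                            sigma1_shape = 0.01,
                                            sigma1_rate = 0.01))
  expect_true(coefficient_report(f1)$excludes_zero)
  expect_true(coefficient_report(f2)$excludes_zero)
})

test_that("fits with too little data or bad panels are rejected", {
  df <- data.frame(dog_id = c("a", "b"), month = c(3L, 3L), value = c(1, 2))
  expect_error(fit_local_level(gait_panel(df, "log"),
                               mcmc = small_mcmc(1)), "fewer than 2 months")
})

test_that("trend comparison reports overlap month by month", {
  pan <- make_recovery_panel(beta = 0, seed = 55)
  fit <- fit_local_level(pan, mcmc = small_mcmc(2))
  self_cmp <- compare_trends(fit, fit)
  expect_true(all(self_cmp$gap == 0))
  expect_false(any(self_cmp$disjoint))

  fit_b <- fit
  fit_b$months <- fit$months + 1
  expect_error(compare_trends(fit, fit_b), "month ranges")
  fit_c <- fit
  fit_c$transform <- "logit100"
  expect_error(compare_trends(fit, fit_c), "transforms")
})

test_that("convergence diagnostics behave on known chains", {
  set.seed(2)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(good), 1.02)
  expect_gt(ess_basic(good), 2000)
  # chains stuck at different levels: rhat must flag them
  bad <- cbind(rnorm(1000, 0), rnorm(1000, 5))
  expect_gt(split_rhat(bad), 2)
  # heavily autocorrelated chain: ESS far below the draw count
  ar <- as.numeric(stats::arima.sim(list(ar = 0.95), 2000))
  expect_lt(ess_basic(cbind(ar)), 500)
})
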