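test_that("the Gelman-Rubin statistic separates mixed from unmixed chains", {
  set.seed(1)
  base <- rnorm(500)
  # exact copies of one draw sequence: between-chain variance is 0
  expect_equal(rhat(cbind(base, base, base), split = FALSE), 1)
  expect_gte(rhat(cbind(base, base, base)), 1)

  good <- matrix(rnorm(2000), 500, 4)
  expect_lt(rhat(good), 1.01)
  bad <- cbind(rnorm(500), rnorm(500, 5))
  expect_gt(rhat(bad), 2)
  # within-chain drift is caught by splitting
  drift <- cbind(c(rnorm(250), rnorm(250, 5)), c(rnorm(250), rnorm(250, 5)))
  expect_gt(rhat(drift), 1.5)
  expect_error(rhat(matrix(1, 100, 3)), "degenerate")
})

test_that("effective sample size reflects autocorrelation", {
  set.seed(2)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_gt(ess(iid), 2500)
  ar <- replicate(4, as.numeric(arima.sim(list(ar = 0.95), 1000)))
  expect_lt(ess(ar), 500)
  expect_error(ess(matrix(0, 100, 2)), "degenerate")
})

test_that("the sampled model has exactly 8 free parameters", {
  trials <- make_small_agent(trials_per_session = 120, seed = 5)
  fit <- fit_hgf(trials, chains = 2, samples = 200, warmup = 100, seed = 1)
  expect_equal(dim(fit$draws)[3], 8L)
  expect_identical(dimnames(fit$draws)[[3]],
                   c("omega", "beta0", "beta1", "beta2", "beta3", "beta4",
                     "beta5", "sigma"))
  expect_equal(nrow(summary(fit)), 8L)
  expect_true(all(summary(fit)$ess > 0))
  expect_s3_class(fit, "hgf_fit")
})

test_that("fits are deterministic under a fixed seed", {
  trials <- make_small_agent(trials_per_session = 120, seed = 7)
  f1 <- fit_hgf(trials, chains = 2, samples = 300, warmup = 150, seed = 3)
  f2 <- fit_hgf(trials, chains = 2, samples = 300, warmup = 150, seed = 3)
  expect_identical(f1$draws, f2$draws)
  expect_identical(summary(f1), summary(f2))
})

test_that("likelihood evaluations are pure", {
  trials <- make_small_agent(trials_per_session = 120, seed = 9)
  trials$excluded <- FALSE
  traj <- hgf_filter(trials$stimulus, hgf_params(-4), session = trials$session)
  reg <- regressor_table(traj, trials)
  p <- response_params(5.83, 0.05, -0.02, -0.15, 0.10, -0.01, sigma = 0.2)
  expect_identical(rt_loglik(trials, reg, p), rt_loglik(trials, reg, p))
})

test_that("with fixed omega and wide priors the posterior matches OLS", {
  trials <- make_small_agent(trials_per_session = 240, seed = 11)
  trials$excluded <- FALSE
  flat <- hgf_priors(beta0 = c(0, 100), beta1 = c(0, 100), beta2 = c(0, 100),
                     beta3 = c(0, 100), beta4 = c(0, 100), beta5 = c(0, 100),
                     sigma = 10)
  fit <- fit_hgf(trials, priors = flat, chains = 2, samples = 1000,
                 warmup = 500, seed = 13, fix_omega = -4)
  traj <- hgf_filter(trials$stimulus, hgf_params(-4), session = trials$session)
  reg <- regressor_table(traj, trials)
  ols <- lm(log(trials$rt_ms) ~ surprise + u_expected + post_error +
              post_reversal, data = reg)
  s <- summary(fit)
  est <- setNames(s$mean, s$parameter)
  mcse <- setNames(s$sd / sqrt(s$ess), s$parameter)
  co <- coef(ols)
  # identifiable coefficients agree within Monte-Carlo error
  expect_lt(abs(est["beta0"] - co["(Intercept)"]), 5 * mcse["beta0"])
  expect_lt(abs(est["beta1"] - co["surprise"]), 5 * mcse["beta1"])
  expect_lt(abs(est["beta4"] - co["post_error"]), 5 * mcse["beta4"])
  expect_lt(abs(est["beta5"] - co["post_reversal"]), 5 * mcse["beta5"])
  # only 7 parameters were sampled
  expect_false("omega" %in% s$parameter)
})

test_that("posterior for omega tightens with more data", {
  sd_of <- function(tps, seed) {
    trials <- make_small_agent(trials_per_session = tps, seed = seed)
    fit <- fit_hgf(trials, chains = 2, samples = 800, warmup = 400,
                   seed = seed)
    s <- summary(fit)
    s$sd[s$parameter == "omega"]
  }
  expect_lt(sd_of(960, 15), sd_of(120, 15))
})

test_that("fit methods expose coefficients, predictions and simulations", {
  trials <- make_small_agent(trials_per_session = 120, seed = 17)
  fit <- fit_hgf(trials, chains = 2, samples = 300, warmup = 150, seed = 5)
  cf <- coef(fit)
  expect_length(cf, 8L)
  mu <- predict(fit)
  expect_length(mu, nrow(trials))
  expect_true(all(is.finite(mu)))
  # predictions live on the log-ms scale of the observed RTs
  expect_lt(abs(mean(mu) - mean(log(trials$rt_ms))), 0.5)
  r <- residuals(fit)
  expect_equal(r, log(trials$rt_ms) - mu)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(nrow(trials), 2L))
  expect_true(all(sim > 0))
  expect_output(print(fit), "chains")
})

test_that("degenerate inputs are rejected", {
  trials <- make_small_agent(trials_per_session = 120, seed = 19)
  expect_error(fit_hgf(trials[1:50, ], chains = 2, samples = 200,
                       warmup = 100), "100 included")
  expect_error(fit_hgf(trials, chains = 2, samples = 100, warmup = 100),
               "warmup")
  expect_warning(fit_hgf(trials, chains = 1, samples = 200, warmup = 100,
                         seed = 2), "single chain")
})
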