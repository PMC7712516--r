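test_that("the sampler is bit-reproducible given a seed", {
  dat <- small_dataset(n_respondents = 14L, seed = 8)
  cfg <- chain_config(burn_in = 50, n_samples = 80, seed = 4)
  f1 <- run_mcmc(dat, model_spec("beta", random_effects = TRUE), cfg)
  f2 <- run_mcmc(dat, model_spec("beta", random_effects = TRUE), cfg)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$deviance, f2$deviance)
  # linear family too
  l1 <- run_mcmc(dat, model_spec("linear"), cfg)
  l2 <- run_mcmc(dat, model_spec("linear"), cfg)
  expect_identical(l1$chains, l2$chains)
})

test_that("linear fixed-effects Gibbs matches the conjugate posterior", {
  # 50-record fixture. With an essentially flat coefficient prior the
  # identified functionals have exact closed forms: the posterior mean of
  # each state's fitted value x' beta is that state's sample mean, and
  # sigma2 | y is inverse gamma around the residual sum of squares.
  full <- small_dataset(n_respondents = 126L, seed = 9)
  picked <- c("111621", "211111", "323644", "545422", "645655")
  dat <- do.call(rbind, lapply(picked, function(s) {
    utils::head(full[full$state_code == s, ], 10)
  }))
  fit <- run_mcmc(dat, model_spec("linear"),
                  chain_config(burn_in = 500, n_samples = 4000, seed = 5))
  pooled <- do.call(rbind, fit$chains)

  states <- unique(dat$state_code)
  group_mean <- tapply(dat$y, dat$state_code, mean)[states]
  ssr <- sum((dat$y - ave(dat$y, dat$state_code))^2)
  n <- nrow(dat); p <- length(states)
  s2_oracle <- (0.001 + ssr / 2) / (0.001 + (n - p) / 2 - 1)

  Xs <- cbind(1, design_matrix(states))
  bcols <- pooled[, c("(Intercept)", sf6d_dummy_names())]
  fitted_draws <- bcols %*% t(Xs)     # draws x states
  for (j in seq_along(states)) {
    x <- fitted_draws[, j]
    mcse <- sf6dbayes:::mcse_mean(x)
    expect_lt(abs(mean(x) - group_mean[j]), 3 * mcse + 1e-6)
  }
  x <- pooled[, "sigma2_eps"]
  expect_lt(abs(mean(x) - s2_oracle),
            4 * sf6dbayes:::mcse_mean(x) + 1e-4)
})

test_that("beta fixed-effects fit recovers generating coefficients", {
  study <- small_study(n_respondents = 56L, seed = 10, true_sigma_b = 0)
  dat <- build_dataset(generate_raw_sg_layer(study), study$respondents)
  fit <- run_mcmc(dat, model_spec("beta"),
                  chain_config(burn_in = 600, n_samples = 1200, seed = 6))
  sm <- summarize_posterior(fit)
  truth <- study$truth$beta
  idx <- match(names(truth), sm$parameter)
  inside <- truth >= sm$lower[idx] & truth <= sm$upper[idx]
  expect_gte(mean(inside), 22 / 26)
  phi_row <- match("phi", sm$parameter)
  expect_lt(abs(sm$mean[phi_row] - study$truth$phi) / study$truth$phi, 0.2)
})

test_that("Metropolis acceptance rates settle in a sane band", {
  dat <- small_dataset(n_respondents = 28L, seed = 11)
  fit <- run_mcmc(dat, model_spec("beta", random_effects = TRUE),
                  fast_config(seed = 7))
  for (acc in fit$acceptance) {
    expect_true(all(acc >= 0.1 & acc <= 0.6))
  }
})

test_that("Gelman-Rubin separates mixed from unmixed chains", {
  with_seed <- sf6dbayes:::with_seed
  same <- with_seed(12, list(matrix(rnorm(10000), ncol = 1,
                                    dimnames = list(NULL, "x")),
                             matrix(rnorm(10000), ncol = 1,
                                    dimnames = list(NULL, "x"))))
  expect_lt(abs(gelman_rubin(same)[["x"]] - 1), 0.05)

  apart <- with_seed(13, list(matrix(rnorm(1000, 0), ncol = 1),
                              matrix(rnorm(1000, 100), ncol = 1)))
  expect_gt(gelman_rubin(apart)[[1]], 10)

  flat <- list(matrix(1, 100, 1), matrix(1, 100, 1))
  expect_equal(gelman_rubin(flat)[[1]], 1)

  expect_error(gelman_rubin(list(matrix(rnorm(100), ncol = 1))),
               "at least 2 chains")
})

test_that("posterior summaries report interval, Rhat and zero-exclusion", {
  dat <- small_dataset(n_respondents = 28L, seed = 14)
  fit <- run_mcmc(dat, model_spec("beta", random_effects = TRUE),
                  fast_config(seed = 8))
  sm <- summarize_posterior(fit)
  expect_true(all(sm$lower <= sm$mean & sm$mean <= sm$upper))
  expect_true(all(is.finite(sm$rhat)))
  # zero-exclusion flag is consistent with the interval itself
  expect_equal(sm$excl_zero, sm$lower > 0 | sm$upper < 0)
  # large effects (PF6 at -0.797 truth) should be flagged, and the flag
  # must mean what it says
  expect_true(sm$excl_zero[sm$parameter == "PF6"])

  # point-mass draws: degenerate interval [c, c]
  vals <- setNames(c(1.5, rep(-0.1, 25), 9),
                   sf6dbayes:::param_layout(
                     sf6dbayes:::build_model_frame(dat, model_spec("beta")),
                     model_spec("beta")))
  cf <- constant_fit(vals, dat)
  smc <- summarize_posterior(cf)
  expect_equal(smc$lower, smc$upper)
  expect_equal(smc$mean, unname(vals[smc$parameter]))
  expect_true(all(smc$excl_zero == (vals[smc$parameter] != 0)))
})

test_that("with almost no data the posterior stays prior-dominated", {
  dat_small <- small_dataset(n_respondents = 14L, seed = 15)
  two <- dat_small[1:2, ]
  cfg <- chain_config(burn_in = 200, n_samples = 500, seed = 9)
  fit2 <- run_mcmc(two, model_spec("linear"), cfg)
  fit_full <- run_mcmc(dat_small, model_spec("linear"), cfg)
  sd2 <- summarize_posterior(fit2)
  sdf <- summarize_posterior(fit_full)
  j <- match("PF6", sd2$parameter)
  expect_gt(sd2$sd[j], 10 * sdf$sd[match("PF6", sdf$parameter)])
})

test_that("alternative priors run and keep the support constraints", {
  dat <- small_dataset(n_respondents = 14L, seed = 16)
  spec <- model_spec("beta", random_effects = TRUE,
                     alt_priors = c("flat_sigma", "phi_uniform_squared"),
                     phi_uniform_bound = 50)
  fit <- run_mcmc(dat, spec, chain_config(burn_in = 150, n_samples = 300,
                                          seed = 10))
  pooled <- do.call(rbind, fit$chains)
  expect_true(all(pooled[, "phi"] > 0 & pooled[, "phi"] < 2500))
  expect_true(all(pooled[, "sigma2_b"] > 0))
})
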