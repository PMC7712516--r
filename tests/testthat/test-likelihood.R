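test_that("beta log-density matches closed forms and normalizes", {
  # mu = 0.5, phi = 2 is Beta(1, 1): the uniform density
  expect_equal(beta_log_density(0.3, 0.5, 2), 0)
  # mu = 0.5, phi = 4 is Beta(2, 2); at the mode the density is 1.5
  expect_equal(beta_log_density(0.5, 0.5, 4), log(1.5))
  # agrees with the standard shape parameterization
  expect_equal(beta_log_density(0.37, 0.62, 7.3),
               dbeta(0.37, 0.62 * 7.3, 0.38 * 7.3, log = TRUE))

  # split at 0.5 so the quadrature can handle the integrable endpoint
  # singularities that appear when a shape parameter drops below 1
  for (mu in c(0.2, 0.5, 0.85)) {
    for (phi in c(0.8, 5, 40)) {
      g <- function(y) exp(beta_log_density(y, mu, phi))
      z <- integrate(g, 0, 0.5, rel.tol = 1e-9)$value +
        integrate(g, 0.5, 1, rel.tol = 1e-9)$value
      expect_equal(z, 1, tolerance = 1e-6)
    }
  }

  expect_error(beta_log_density(0, 0.5, 2), "strictly")
  expect_error(beta_log_density(1, 0.5, 2), "strictly")
  expect_error(beta_log_density(0.5, 1, 2), "strictly")
  expect_error(beta_log_density(0.5, 0.5, 0), "positive")
})

test_that("beta moments follow the mean/precision parameterization", {
  m <- beta_moments(0.5, 9)
  expect_equal(m$mean, 0.5)
  expect_equal(m$variance, 0.025)

  # variance shrinks monotonically in phi
  v <- vapply(c(1, 5, 20, 100, 1e4), function(phi) {
    beta_moments(0.5, phi)$variance
  }, numeric(1))
  expect_true(all(diff(v) < 0))
  expect_lt(v[length(v)], 1e-4)

  # Monte-Carlo check at (0.7, 10)
  draws <- sf6dbayes:::with_seed(11, rbeta(1e5, 0.7 * 10, 0.3 * 10))
  expect_equal(var(draws), 0.21 / 11, tolerance = 0.02)
  expect_error(beta_moments(0, 5), "strictly")
})

test_that("linear predictor and inverse link behave as in the models", {
  x_full <- c(1, rep(0, 25))
  beta <- c(2.175, rnorm(25))
  expect_equal(linear_predictor(x_full, beta), 2.175)
  expect_equal(mean_response(2.175, "beta"), 0.898, tolerance = 1e-3)
  expect_equal(mean_response(0, "beta"), 0.5)
  expect_equal(mean_response(0.7, "linear"), 0.7)
  expect_equal(linear_predictor(x_full, beta, b = 0.3), 2.475)
  expect_error(linear_predictor(c(1, 0), beta), "dimension mismatch")

  # a negative dummy coefficient strictly decreases the beta-family mean
  x2 <- x_full; x2[2] <- 1
  beta_neg <- beta; beta_neg[2] <- -0.4
  expect_lt(mean_response(linear_predictor(x2, beta_neg), "beta"),
            mean_response(linear_predictor(x_full, beta_neg), "beta"))
})

test_that("log_posterior equals a directly coded sum on a small fixture", {
  dat <- small_dataset(n_respondents = 14L, seed = 6)
  dat <- dat[1:10, ]
  spec <- model_spec("beta", random_effects = TRUE)
  resp_ids <- unique(as.character(dat$respondent_id))
  params <- list(
    beta = setNames(c(1.8, rnorm(25, -0.2, 0.1)),
                    c("(Intercept)", sf6d_dummy_names())),
    phi = 8,
    b = setNames(rnorm(length(resp_ids), 0, 0.2), resp_ids),
    sigma2_b = 0.09
  )

  # independent direct computation, term by term
  X <- cbind(1, design_matrix(dat$state_code))
  eta <- drop(X %*% params$beta) +
    params$b[as.character(dat$respondent_id)]
  mu <- 1 / (1 + exp(-eta))
  loglik <- sum(dbeta(dat$y, mu * params$phi, (1 - mu) * params$phi,
                      log = TRUE))
  lp_beta <- sum(dnorm(params$beta, 0, 1000, log = TRUE))
  ig <- function(x, a, r) a * log(r) - lgamma(a) - (a + 1) * log(x) - r / x
  lp_phi <- ig(params$phi, 0.001, 0.001)
  lp_b <- sum(dnorm(params$b, 0, sqrt(params$sigma2_b), log = TRUE))
  lp_s2b <- ig(params$sigma2_b, 0.001, 0.001)
  oracle <- loglik + lp_beta + lp_phi + lp_b + lp_s2b

  expect_equal(log_posterior(spec, params, dat), oracle, tolerance = 1e-8)

  # single-record beta-family case reduces to one density + priors
  one <- dat[1, ]
  spec_fe <- model_spec("beta")
  params_fe <- params[c("beta", "phi")]
  eta1 <- sum(cbind(1, design_matrix(one$state_code)) * params_fe$beta)
  expect_equal(log_posterior(spec_fe, params_fe, one),
               beta_log_density(one$y, plogis(eta1), params_fe$phi) +
                 lp_beta + lp_phi,
               tolerance = 1e-8)
})

test_that("log_posterior decreases into the prior tails", {
  dat <- small_dataset(n_respondents = 14L, seed = 7)
  spec <- model_spec("beta", random_effects = TRUE)
  resp_ids <- unique(as.character(dat$respondent_id))
  base <- list(
    beta = setNames(c(1.8, rep(-0.2, 25)),
                    c("(Intercept)", sf6d_dummy_names())),
    phi = 8,
    b = setNames(rep(0, length(resp_ids)), resp_ids),
    sigma2_b = 0.1
  )
  lp <- vapply(c(0.1, 10, 1000, 1e5), function(s2) {
    p <- base; p$sigma2_b <- s2
    log_posterior(spec, p, dat)
  }, numeric(1))
  expect_true(all(diff(lp) < 0))
  # off-support values are rejected outright
  bad <- base; bad$phi <- -1
  expect_equal(log_posterior(spec, bad, dat), -Inf)
})
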