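#' Log-density of the mean/precision parameterized beta distribution
#'
#' The beta density used for utilities in (0, 1) is parameterized by its
#' mean `mu` and precision `phi`, i.e. `y ~ Beta(mu * phi, (1 - mu) * phi)`,
#' so that `E(y) = mu` and `Var(y) = mu * (1 - mu) / (1 + phi)`.
#'
#' @param y Values strictly in (0, 1).
#' @param mu Mean, strictly in (0, 1).
#' @param phi Precision, strictly positive.
#' @return Log-density, vectorized over the arguments.
#' @export
beta_log_density <- function(y, mu, phi) {
  if (any(y <= 0 | y >= 1)) stop("`y` must lie strictly in (0, 1)",
                                 call. = FALSE)
  if (any(mu <= 0 | mu >= 1)) stop("`mu` must lie strictly in (0, 1)",
                                   call. = FALSE)
  if (any(phi <= 0)) stop("`phi` must be positive", call. = FALSE)
  a <- mu * phi
  b <- (1 - mu) * phi
  lgamma(phi) - lgamma(a) - lgamma(b) + (a - 1) * log(y) +
    (b - 1) * log1p(-y)
}

#' Mean and variance of the mean/precision beta distribution
#'
#' @inheritParams beta_log_density
#' @return List with elements `mean` (`mu`) and `variance`
#'   (`mu * (1 - mu) / (1 + phi)`).
#' @export
beta_moments <- function(mu, phi) {
  if (any(mu <= 0 | mu >= 1)) stop("`mu` must lie strictly in (0, 1)",
                                   call. = FALSE)
  if (any(phi <= 0)) stop("`phi` must be positive", call. = FALSE)
  list(mean = mu, variance = mu * (1 - mu) / (1 + phi))
}

#' Linear predictor of the utility models
#'
#' `eta = x' beta (+ b)`; the beta family maps it to a mean utility through
#' the logistic inverse link, the linear family uses it directly.
#'
#' @param x Design vector, or matrix with one row per record, aligned with
#'   `beta` (including the intercept column).
#' @param beta Coefficient vector.
#' @param b Optional random intercept(s), default 0.
#' @return Numeric vector `eta`.
#' @seealso [mean_response()]
#' @export
linear_predictor <- function(x, beta, b = 0) {
  if (is.matrix(x)) {
    if (ncol(x) != length(beta)) stop("dimension mismatch", call. = FALSE)
    drop(x %*% beta) + b
  } else {
    if (length(x) != length(beta)) stop("dimension mismatch", call. = FALSE)
    sum(x * beta) + b
  }
}

#' Map a linear predictor to the mean response
#'
#' @param eta Linear predictor values.
#' @param family `"beta"` (logistic inverse link) or `"linear"` (identity).
#' @return Mean utilities.
#' @export
mean_response <- function(eta, family = c("beta", "linear")) {
  family <- match.arg(family)
  if (family == "beta") stats::plogis(eta) else eta
}

#' Names of the nine covariate design columns
#' @return Character vector: AGE, GENDER, DEGREE, HOUSING1, HOUSING2,
#'   INCOME1, INCOME2, MS1, MS2.
#' @export
covariate_names <- function() {
  c("AGE", "GENDER", "DEGREE", "HOUSING1", "HOUSING2",
    "INCOME1", "INCOME2", "MS1", "MS2")
}

# Covariate design columns from raw profile variables. Age enters in years;
# gender/degree are 0/1; the three-category variables (housing, income,
# marital status) are coded with category 1 as reference.
covariate_matrix <- function(data) {
  need <- c("age", "gender", "degree", "housing", "income", "marital_status")
  if (!all(need %in% names(data))) {
    stop("covariate model needs respondent profiles (columns ",
         paste(need, collapse = ", "), ")", call. = FALSE)
  }
  cbind(AGE = as.numeric(data$age),
        GENDER = as.numeric(data$gender),
        DEGREE = as.numeric(data$degree),
        HOUSING1 = as.numeric(data$housing == 2),
        HOUSING2 = as.numeric(data$housing == 3),
        INCOME1 = as.numeric(data$income == 2),
        INCOME2 = as.numeric(data$income == 3),
        MS1 = as.numeric(data$marital_status == 2),
        MS2 = as.numeric(data$marital_status == 3))
}

# Full model frame for a fit: response, design matrix (intercept + 25 state
# dummies [+ 9 covariates]), respondent index for random effects.
build_model_frame <- function(data, spec) {
  X <- cbind(`(Intercept)` = 1, design_matrix(data$state_code))
  rownames(X) <- NULL
  if (spec$covariates) X <- cbind(X, covariate_matrix(data))
  y <- data$y
  if (spec$family == "beta" && any(y <= 0 | y >= 1)) {
    stop("beta-family models require 0 < y < 1 for every record; ",
         "see compress_boundary() for boundary values", call. = FALSE)
  }
  resp_ids <- unique(as.character(data$respondent_id))
  list(y = as.numeric(y),
       X = X,
       resp = match(as.character(data$respondent_id), resp_ids),
       resp_ids = resp_ids)
}

# log prior density pieces ---------------------------------------------------

log_ig <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

log_prior_phi <- function(phi, spec) {
  if ("phi_uniform_squared" %in% spec$alt_priors) {
    # phi = U^2, U ~ Uniform(0, a): p(phi) = 1/(2 a sqrt(phi)) on (0, a^2)
    if (phi >= spec$phi_uniform_bound^2) return(-Inf)
    -log(2 * spec$phi_uniform_bound) - 0.5 * log(phi)
  } else {
    log_ig(phi, spec$prior_ig_shape, spec$prior_ig_rate)
  }
}

log_prior_sigma2_b <- function(s2, spec) {
  if ("flat_sigma" %in% spec$alt_priors) {
    # flat prior on sigma: p(sigma^2) proportional to 1/sigma
    -0.5 * log(s2)
  } else {
    log_ig(s2, spec$prior_ig_shape, spec$prior_ig_rate)
  }
}

#' Unnormalized log posterior of a model
#'
#' Sum of the log-likelihood over all records, the random-effect density
#' when enabled, and the log priors. Mainly useful for testing the sampler
#' against direct computation.
#'
#' @param spec An `"sf6d_model_spec"`.
#' @param params Named list with `beta` (aligned with the design matrix),
#'   and depending on the model: `phi` (beta family), `sigma2_eps` (linear
#'   family), `b` and `sigma2_b` (random-effects models).
#' @param data Adjusted valuation data as from [build_dataset()].
#' @return Log posterior density (unnormalized), `-Inf` off the support.
#' @export
log_posterior <- function(spec, params, data) {
  mf <- build_model_frame(data, spec)
  b_of <- if (spec$random_effects) params$b[mf$resp] else 0
  eta <- drop(mf$X %*% params$beta) + b_of
  lp <- 0
  if (spec$family == "beta") {
    if (params$phi <= 0) return(-Inf)
    mu <- stats::plogis(eta)
    if (any(mu <= 0 | mu >= 1)) return(-Inf)
    lp <- lp + sum(beta_log_density(mf$y, mu, params$phi)) +
      log_prior_phi(params$phi, spec)
  } else {
    if (params$sigma2_eps <= 0) return(-Inf)
    lp <- lp + sum(stats::dnorm(mf$y, eta, sqrt(params$sigma2_eps),
                                log = TRUE)) +
      log_ig(params$sigma2_eps, spec$prior_ig_shape, spec$prior_ig_rate)
  }
  lp <- lp + sum(stats::dnorm(params$beta, 0,
                              sqrt(spec$prior_beta_variance), log = TRUE))
  if (spec$random_effects) {
    if (params$sigma2_b <= 0) return(-Inf)
    lp <- lp + sum(stats::dnorm(params$b, 0, sqrt(params$sigma2_b),
                                log = TRUE)) +
      log_prior_sigma2_b(params$sigma2_b, spec)
  }
  lp
}
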