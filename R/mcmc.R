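#' Fit a utility model by Metropolis-within-Gibbs MCMC
#'
#' Runs the estimation protocol used for all six model variants: multiple
#' parallel chains from overdispersed initial values, a burn-in period that
#' is discarded, and a fixed number of retained draws per chain.
#'
#' Conjugate coordinates are updated by Gibbs steps: for the linear family,
#' `beta | sigma2` (multivariate normal), `sigma2_eps | beta`
#' (inverse gamma), and the random intercepts `b | rest`; in both families
#' the random-effect variance `sigma2_b | b` is inverse gamma (or the
#' flat-sigma alternative). Non-conjugate coordinates of the beta family
#' (`beta` as one block, `phi`, and each `b_i`) use Gaussian random-walk
#' Metropolis, with `phi` and the variances sampled on the log scale. The
#' `beta` block proposal adapts both a global scale (Robbins-Monro toward
#' the target acceptance rate) and its covariance (running posterior
#' covariance estimate); scalar proposals adapt their scales only. All
#' adaptation is frozen at the end of burn-in. The conditional deviance
#' `-2 log L` is recorded at every retained draw.
#'
#' @param data Adjusted valuations (columns `respondent_id`, `state_code`,
#'   `y`, plus profile columns for covariate models), e.g. from
#'   [build_dataset()].
#' @param spec An `"sf6d_model_spec"`.
#' @param config An `"sf6d_chain_config"`.
#' @return An object of class `"sf6d_fit"`: per-chain draw matrices (one
#'   column per scalar parameter), deviance traces, acceptance rates, and
#'   the model frame used.
#' @examples
#' study <- generate_study(generator_config(n_respondents = 14, seed = 1))
#' dat <- build_dataset(generate_raw_sg_layer(study), study$respondents)
#' fit <- run_mcmc(dat, model_spec("beta"),
#'                 chain_config(burn_in = 100, n_samples = 200, seed = 1))
#' @export
run_mcmc <- function(data, spec, config = chain_config()) {
  stopifnot(inherits(spec, "sf6d_model_spec"),
            inherits(config, "sf6d_chain_config"))
  if (nrow(data) == 0) stop("`data` is empty", call. = FALSE)
  mf <- build_model_frame(data, spec)
  if (spec$random_effects && length(mf$resp_ids) < 2) {
    stop("random-effects models need at least 2 respondents", call. = FALSE)
  }
  runner <- if (spec$family == "linear") run_chain_linear else run_chain_beta
  chains <- vector("list", config$n_chains)
  for (k in seq_len(config$n_chains)) {
    chains[[k]] <- with_seed(config$seed + k - 1L,
                             runner(mf, spec, config, k))
  }
  structure(
    list(spec = spec,
         config = config,
         param_names = colnames(chains[[1]]$draws),
         chains = lapply(chains, `[[`, "draws"),
         deviance = lapply(chains, `[[`, "deviance"),
         acceptance = lapply(chains, `[[`, "acceptance"),
         mf = mf),
    class = "sf6d_fit"
  )
}

#' @export
print.sf6d_fit <- function(x, ...) {
  cat("Bayesian SF-6D valuation model:", model_name(x$spec), "\n")
  cat(sprintf("  %d chain(s), %d retained draws each (burn-in %d)\n",
              length(x$chains), nrow(x$chains[[1]]), x$config$burn_in))
  cat(sprintf("  %d records, %d parameters, max Rhat %.3f\n",
              length(x$mf$y), length(x$param_names),
              max(gelman_rubin(x))))
  invisible(x)
}

#' Posterior-mean coefficients of a fit
#' @param object An `"sf6d_fit"`.
#' @param ... Unused.
#' @return Named numeric vector of posterior means for the regression
#'   coefficients (intercept, state dummies, covariates if present).
#' @export
coef.sf6d_fit <- function(object, ...) {
  pooled <- do.call(rbind, object$chains)
  cm <- colMeans(pooled)
  cm[colnames(object$mf$X)]
}

# ---------------------------------------------------------------------------
# chain runners (called with the RNG already seeded for this chain)

param_layout <- function(mf, spec) {
  nm <- colnames(mf$X)
  nm <- c(nm, if (spec$family == "beta") "phi" else "sigma2_eps")
  if (spec$random_effects) {
    nm <- c(nm, "sigma2_b", paste0("b[", mf$resp_ids, "]"))
  }
  nm
}

init_values <- function(mf, spec, config, chain) {
  p <- ncol(mf$X)
  # start near the mode: least squares on the (logit-transformed) response;
  # fall back to an intercept-only start if the solve fails
  z <- if (spec$family == "beta") {
    stats::qlogis(pmin(pmax(mf$y, 1e-4), 1 - 1e-4))
  } else {
    mf$y
  }
  beta <- tryCatch(
    drop(solve(crossprod(mf$X) + diag(1e-8, p), crossprod(mf$X, z))),
    error = function(e) {
      b0 <- rep(0, p)
      b0[1] <- mean(z)
      b0
    })
  st <- list(beta = beta, phi = 10, s2e = 0.1, s2b = 0.1,
             b = rep(0, length(mf$resp_ids)))
  if (chain > 1L) {
    j <- config$init_jitter_sd
    st$beta <- st$beta + stats::rnorm(p, 0, j)
    st$phi <- exp(log(st$phi) + stats::rnorm(1, 0, 2 * j))
    st$s2e <- exp(log(st$s2e) + stats::rnorm(1, 0, 2 * j))
    st$s2b <- exp(log(st$s2b) + stats::rnorm(1, 0, 2 * j))
  }
  st
}

sample_sigma2_b <- function(b, spec) {
  m <- length(b)
  if ("flat_sigma" %in% spec$alt_priors) {
    1 / stats::rgamma(1, shape = (m - 1) / 2, rate = sum(b^2) / 2)
  } else {
    1 / stats::rgamma(1, shape = spec$prior_ig_shape + m / 2,
                      rate = spec$prior_ig_rate + sum(b^2) / 2)
  }
}

run_chain_linear <- function(mf, spec, config, chain) {
  y <- mf$y; X <- mf$X
  n <- length(y); p <- ncol(X)
  re <- spec$random_effects
  resp <- mf$resp
  m <- length(mf$resp_ids)
  ni <- tabulate(resp, m)
  a0 <- spec$prior_ig_shape; r0 <- spec$prior_ig_rate
  V0 <- spec$prior_beta_variance
  XtX <- crossprod(X)

  st <- init_values(mf, spec, config, chain)
  beta <- st$beta; s2e <- st$s2e; s2b <- st$s2b
  b <- st$b
  boff <- if (re) b[resp] else 0

  nm <- param_layout(mf, spec)
  keep <- config$n_samples
  draws <- matrix(NA_real_, keep, length(nm), dimnames = list(NULL, nm))
  dev <- numeric(keep)

  total <- config$burn_in + keep
  for (t in seq_len(total)) {
    # beta | sigma2, b  (conjugate multivariate normal)
    A <- XtX / s2e
    diag(A) <- diag(A) + 1 / V0
    R <- chol(A)
    rhs <- crossprod(X, y - boff) / s2e
    mu_beta <- backsolve(R, forwardsolve(t(R), rhs))
    beta <- drop(mu_beta + backsolve(R, stats::rnorm(p)))
    eta_x <- drop(X %*% beta)

    if (re) {
      # b_i | rest  (conjugate normal, vectorized over respondents)
      r_i <- drop(rowsum(y - eta_x, resp))
      prec <- ni / s2e + 1 / s2b
      b <- stats::rnorm(m, (r_i / s2e) / prec, sqrt(1 / prec))
      # interweaving translation: shift intercept by delta, all b_i by
      # -delta; the likelihood is invariant, delta | rest is normal, and
      # the move decorrelates the intercept from the random-effect mean
      prec_d <- m / s2b + 1 / V0
      delta <- stats::rnorm(1, (sum(b) / s2b - beta[1] / V0) / prec_d,
                            sqrt(1 / prec_d))
      beta[1] <- beta[1] + delta
      b <- b - delta
      eta_x <- eta_x + delta
      boff <- b[resp]
    }

    resid <- y - eta_x - boff
    s2e <- 1 / stats::rgamma(1, shape = a0 + n / 2,
                             rate = r0 + sum(resid^2) / 2)
    if (re) s2b <- sample_sigma2_b(b, spec)

    if (t > config$burn_in) {
      i <- t - config$burn_in
      draws[i, ] <- c(beta, s2e, if (re) c(s2b, b))
      dev[i] <- -2 * sum(stats::dnorm(y, eta_x + boff, sqrt(s2e),
                                      log = TRUE))
    }
  }
  list(draws = draws, deviance = dev,
       acceptance = c(beta = 1, if (re) c(b = 1)))
}

run_chain_beta <- function(mf, spec, config, chain) {
  y <- mf$y; X <- mf$X
  n <- length(y); p <- ncol(X)
  re <- spec$random_effects
  resp <- mf$resp
  m <- length(mf$resp_ids)
  V0 <- spec$prior_beta_variance
  target <- config$target_acceptance
  ly <- log(y); l1y <- log1p(-y)

  loglik_vec <- function(eta, phi) {
    mu <- stats::plogis(eta)
    a <- mu * phi
    bb <- (1 - mu) * phi
    lgamma(phi) - lgamma(a) - lgamma(bb) + (a - 1) * ly + (bb - 1) * l1y
  }
  loglik_at <- function(eta_sub, phi, idx) {
    mu <- stats::plogis(eta_sub)
    a <- mu * phi
    bb <- (1 - mu) * phi
    lgamma(phi) - lgamma(a) - lgamma(bb) + (a - 1) * ly[idx] +
      (bb - 1) * l1y[idx]
  }
  # per-coordinate support: the dummy columns are sparse, so a scalar move
  # on coordinate j only touches the records whose state activates dummy j
  idx_of <- lapply(seq_len(p), function(j) which(X[, j] != 0))
  x_of <- lapply(seq_len(p), function(j) X[idx_of[[j]], j])

  st <- init_values(mf, spec, config, chain)
  beta <- st$beta; phi <- st$phi; s2b <- st$s2b
  b <- st$b
  boff <- if (re) b[resp] else numeric(n)
  eta_x <- drop(X %*% beta)
  llv <- loglik_vec(eta_x + boff, phi)
  ll <- sum(llv)
  if (!is.finite(ll)) stop("non-finite log posterior at initialization",
                           call. = FALSE)

  # adaptation state: global log-scale for the beta block plus a running
  # estimate of the posterior covariance (Welford). Until enough draws have
  # accumulated the proposal uses the design-based covariance (X'X)^-1,
  # which already carries the intercept/dummy correlation structure.
  log_lam <- 0
  base_scale <- 2.38 / sqrt(p)
  wf_n <- 0L
  wf_mean <- numeric(p)
  wf_M2 <- matrix(0, p, p)
  Rprop <- tryCatch(chol(solve(crossprod(X) + diag(1e-8, p))),
                    error = function(e) NULL)
  if (is.null(Rprop)) {
    log_lam <- log(0.05)
    base_scale <- 1
  }
  cov_from <- max(200L, 4L * p)
  ls_phi <- log(0.3)
  ls_b <- rep(log(0.5), m)
  ls_co <- rep(log(0.1), p)   # per-coordinate scan scales
  acc_beta <- 0; acc_phi <- 0; acc_b <- 0; acc_co <- 0; n_post <- 0L

  nm <- param_layout(mf, spec)
  keep <- config$n_samples
  draws <- matrix(NA_real_, keep, length(nm), dimnames = list(NULL, nm))
  dev <- numeric(keep)

  total <- config$burn_in + keep
  for (t in seq_len(total)) {
    adapting <- t <= config$burn_in
    gam <- t^(-0.6)

    # -- beta block: adaptive Gaussian random-walk Metropolis
    z <- stats::rnorm(p)
    step <- if (is.null(Rprop)) exp(log_lam) * z
            else exp(log_lam) * base_scale * drop(crossprod(Rprop, z))
    prop <- beta + step
    eta2 <- drop(X %*% prop)
    llv2 <- loglik_vec(eta2 + boff, phi)
    ll2 <- sum(llv2)
    lacc <- ll2 - ll + (sum(beta^2) - sum(prop^2)) / (2 * V0)
    apr <- if (is.finite(lacc)) min(1, exp(lacc)) else 0
    if (stats::runif(1) < apr) {
      beta <- prop; eta_x <- eta2; llv <- llv2; ll <- ll2
    }
    if (adapting) {
      log_lam <- log_lam + gam * (apr - target)
      wf_n <- wf_n + 1L
      d1 <- beta - wf_mean
      wf_mean <- wf_mean + d1 / wf_n
      wf_M2 <- wf_M2 + tcrossprod(d1, beta - wf_mean)
      if (wf_n == cov_from ||
          (wf_n > cov_from && wf_n %% 25L == 0L)) {
        C <- wf_M2 / (wf_n - 1L) + diag(1e-10, p)
        Rnew <- tryCatch(chol(C), error = function(e) NULL)
        if (!is.null(Rnew)) {
          if (is.null(Rprop)) log_lam <- 0  # rescale once on switch
          Rprop <- Rnew
          base_scale <- 2.38 / sqrt(p)
        }
      }
    } else {
      acc_beta <- acc_beta + apr
    }

    # -- coordinate scan (two sweeps): scalar random-walk Metropolis per
    # coefficient, evaluating only the records the coordinate touches
    apr_sum <- 0
    for (j in rep(seq_len(p), 2L)) {
      idx <- idx_of[[j]]
      dlt <- stats::rnorm(1, 0, exp(ls_co[j]))
      eta_j <- eta_x[idx] + boff[idx] + dlt * x_of[[j]]
      ll_j2 <- loglik_at(eta_j, phi, idx)
      bj2 <- beta[j] + dlt
      lacc <- sum(ll_j2) - sum(llv[idx]) +
        (beta[j]^2 - bj2^2) / (2 * V0)
      apr <- if (is.finite(lacc)) min(1, exp(lacc)) else 0
      if (stats::runif(1) < apr) {
        beta[j] <- bj2
        eta_x[idx] <- eta_x[idx] + dlt * x_of[[j]]
        llv[idx] <- ll_j2
      }
      if (adapting) ls_co[j] <- ls_co[j] + gam * (apr - target)
      apr_sum <- apr_sum + apr
    }
    ll <- sum(llv)
    if (!adapting) acc_co <- acc_co + apr_sum / (2 * p)

    # -- phi: random walk on log phi (prior + Jacobian in the ratio)
    lphi2 <- log(phi) + stats::rnorm(1, 0, exp(ls_phi))
    phi2 <- exp(lphi2)
    llv2 <- loglik_vec(eta_x + boff, phi2)
    ll2 <- sum(llv2)
    lacc <- ll2 - ll +
      log_prior_phi(phi2, spec) - log_prior_phi(phi, spec) +
      lphi2 - log(phi)
    apr <- if (is.finite(lacc)) min(1, exp(lacc)) else 0
    if (stats::runif(1) < apr) {
      phi <- phi2; llv <- llv2; ll <- ll2
    }
    if (adapting) ls_phi <- ls_phi + gam * (apr - target)
    else acc_phi <- acc_phi + apr

    if (re) {
      # -- b_i: scalar random-walk Metropolis, vectorized over respondents
      b2 <- b + stats::rnorm(m, 0, exp(ls_b))
      llv2 <- loglik_vec(eta_x + b2[resp], phi)
      d_ll <- drop(rowsum(llv2 - llv, resp))
      d_ll[is.na(d_ll)] <- -Inf
      lacc_i <- d_ll + (b^2 - b2^2) / (2 * s2b)
      apr_i <- pmin(1, exp(pmin(lacc_i, 0)))
      acc_i <- stats::runif(m) < apr_i
      if (any(acc_i)) {
        b[acc_i] <- b2[acc_i]
        rows <- acc_i[resp]
        llv[rows] <- llv2[rows]
        ll <- sum(llv)
        boff <- b[resp]
      }
      if (adapting) ls_b <- ls_b + gam * (apr_i - target)
      else acc_b <- acc_b + mean(apr_i)

      # interweaving translation (see run_chain_linear): delta | rest is
      # normal and the likelihood is invariant under
      # (intercept, b) -> (intercept + delta, b - delta)
      prec_d <- m / s2b + 1 / V0
      delta <- stats::rnorm(1, (sum(b) / s2b - beta[1] / V0) / prec_d,
                            sqrt(1 / prec_d))
      beta[1] <- beta[1] + delta
      b <- b - delta
      eta_x <- eta_x + delta
      boff <- b[resp]

      # -- sigma2_b | b: Gibbs
      s2b <- sample_sigma2_b(b, spec)
    }

    if (t > config$burn_in) {
      n_post <- n_post + 1L
      i <- t - config$burn_in
      draws[i, ] <- c(beta, phi, if (re) c(s2b, b))
      dev[i] <- -2 * ll
    }
  }
  list(draws = draws, deviance = dev,
       acceptance = c(beta = acc_beta / n_post,
                      coord = acc_co / n_post,
                      phi = acc_phi / n_post,
                      if (re) c(b = acc_b / n_post)))
}
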