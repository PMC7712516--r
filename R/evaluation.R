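#' Posterior predicted mean utility of health states
#'
#' For each retained draw, computes the population-level mean utility of
#' each state with the random effect set to 0 (the "median respondent"
#' plug-in convention) and, for covariate models, covariates at their
#' reference coding (zero). The beta family applies the logistic inverse
#' link to `x' beta`; the linear family uses `x' beta` directly. Returns
#' the mean and standard deviation over draws.
#'
#' Setting `marginal = TRUE` instead averages, within each draw, over
#' `n_marginal` simulated random intercepts `b ~ N(0, sigma2_b)` (a
#' Monte-Carlo population mean rather than the median-respondent value);
#' this only differs from the plug-in version for nonlinear (beta-family)
#' links.
#'
#' @param fit An `"sf6d_fit"`.
#' @param states Character vector of state codes.
#' @param marginal Average over the random-effect distribution?
#' @param n_marginal Random intercepts per draw when `marginal = TRUE`.
#' @return Data frame with `state_code`, `predicted_mean`, `predicted_sd`.
#' @export
predict_state_utility <- function(fit, states, marginal = FALSE,
                                  n_marginal = 30L) {
  stopifnot(inherits(fit, "sf6d_fit"))
  Xs <- cbind(`(Intercept)` = 1, design_matrix(states))
  pooled <- do.call(rbind, fit$chains)
  bdraws <- pooled[, colnames(fit$mf$X), drop = FALSE]
  bdraws <- bdraws[, colnames(Xs), drop = FALSE]  # covariates at reference
  eta <- bdraws %*% t(Xs)                         # draws x states
  if (fit$spec$family == "beta") {
    if (marginal && fit$spec$random_effects) {
      s_b <- sqrt(pooled[, "sigma2_b"])
      mu <- with_seed(fit$config$seed, {
        zs <- stats::rnorm(n_marginal)
        acc <- 0
        for (z in zs) acc <- acc + stats::plogis(eta + s_b * z)
        acc / n_marginal
      })
    } else {
      mu <- stats::plogis(eta)
    }
  } else {
    mu <- eta
  }
  data.frame(state_code = states,
             predicted_mean = colMeans(mu),
             predicted_sd = apply(mu, 2, stats::sd),
             stringsAsFactors = FALSE)
}

#' Plug-in state utilities from a coefficient vector
#'
#' Deterministic predicted utilities from a single coefficient vector
#' (e.g. posterior means): `mu = inverse-logit(x' beta)` for the beta
#' family, `x' beta` for the linear family. This is the predictor used for
#' large-scale audits where carrying full posterior draws is unnecessary.
#'
#' @param coefs Named coefficient vector containing `(Intercept)` and the
#'   25 state-dummy names; or an `"sf6d_fit"`, whose posterior-mean
#'   coefficients are used.
#' @param states Character vector of state codes.
#' @param family `"beta"` or `"linear"`; ignored (taken from the fit) when
#'   `coefs` is a fit.
#' @return Named numeric vector of utilities, one per state.
#' @export
state_utilities <- function(coefs, states, family = c("beta", "linear")) {
  if (inherits(coefs, "sf6d_fit")) {
    family <- coefs$spec$family
    coefs <- coef(coefs)
  } else {
    family <- match.arg(family)
  }
  need <- c("(Intercept)", sf6d_dummy_names())
  if (!all(need %in% names(coefs))) {
    stop("`coefs` must be named and include the intercept and the 25 ",
         "state dummies", call. = FALSE)
  }
  Xs <- cbind(`(Intercept)` = 1, design_matrix(states))
  eta <- drop(Xs %*% coefs[colnames(Xs)])
  stats::setNames(mean_response(eta, family), states)
}

#' Mean prediction error (mean absolute error)
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return `mean(abs(observed - predicted))`.
#' @export
mpe <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0) {
    stop("`observed` and `predicted` must have equal, nonzero length",
         call. = FALSE)
  }
  mean(abs(observed - predicted))
}

#' Root-mean-square error
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0) {
    stop("`observed` and `predicted` must have equal, nonzero length",
         call. = FALSE)
  }
  sqrt(mean((observed - predicted)^2))
}

#' Observed vs predicted utilities for the states in a dataset
#'
#' One row per distinct state: the observed mean utility and the model's
#' posterior predicted mean and SD.
#'
#' @param fit An `"sf6d_fit"`.
#' @param data Adjusted valuation data (for the observed means).
#' @return Data frame with `state_code`, `observed_mean`, `predicted_mean`,
#'   `predicted_sd`, plus attributes `mpe` and `rmse` computed over the
#'   state means.
#' @export
prediction_table <- function(fit, data) {
  obs <- state_summaries(data)
  pred <- predict_state_utility(fit, obs$state_code)
  out <- data.frame(state_code = obs$state_code,
                    observed_mean = obs$mean,
                    predicted_mean = pred$predicted_mean,
                    predicted_sd = pred$predicted_sd,
                    stringsAsFactors = FALSE)
  attr(out, "mpe") <- mpe(out$observed_mean, out$predicted_mean)
  attr(out, "rmse") <- rmse(out$observed_mean, out$predicted_mean)
  out
}

#' Model comparison metrics
#'
#' MPE and RMSE can be aggregated at the record level (residuals of all
#' individual valuations) or at the state-mean level (49-state observed vs
#' predicted means); both appear in applied work and differ substantially,
#' so the level is explicit.
#'
#' @param fit An `"sf6d_fit"`.
#' @param data Adjusted valuation data the model was fitted to.
#' @param aggregation `"state_mean"` or `"record"`.
#' @return List with `mpe`, `rmse`, `dic` (list of Dbar/pD/DIC) and
#'   `aggregation`.
#' @export
evaluation_metrics <- function(fit, data,
                               aggregation = c("state_mean", "record")) {
  aggregation <- match.arg(aggregation)
  if (aggregation == "state_mean") {
    tab <- prediction_table(fit, data)
    o <- tab$observed_mean; p <- tab$predicted_mean
  } else {
    pred <- predict_state_utility(fit, unique(data$state_code))
    p <- pred$predicted_mean[match(data$state_code, pred$state_code)]
    o <- data$y
  }
  list(mpe = mpe(o, p), rmse = rmse(o, p), dic = dic(fit),
       aggregation = aggregation)
}

#' Audit predicted utilities for monotonicity violations
#'
#' Utility should not increase when any single dimension worsens by one
#' level. For each adjacent pair, the worse state is the one with the
#' higher level in the differing dimension; the pair is a violation when
#' the worse state's predicted utility is strictly greater than the better
#' state's (`non_strict`, the default) or greater-or-equal (`strict`,
#' which also counts ties).
#'
#' @param fit An `"sf6d_fit"` or a named coefficient vector (see
#'   [state_utilities()]).
#' @param pairs Data frame of adjacent pairs from
#'   [sample_adjacent_pairs()].
#' @param strictness `"non_strict"` or `"strict"`.
#' @param family Used only when `fit` is a coefficient vector.
#' @return List with `n_pairs`, `n_violations`, `fraction_violating`,
#'   `strictness`.
#' @export
monotonicity_audit <- function(fit, pairs,
                               strictness = c("non_strict", "strict"),
                               family = c("beta", "linear")) {
  strictness <- match.arg(strictness)
  codes <- unique(c(pairs$state_a, pairs$state_b))
  u <- state_utilities(fit, codes, family = family)
  la <- state_levels(pairs$state_a)
  lb <- state_levels(pairs$state_b)
  dif <- la != lb
  if (any(rowSums(dif) != 1L)) {
    stop("pairs must differ in exactly one dimension", call. = FALSE)
  }
  d <- max.col(dif)  # the differing dimension per pair
  lev_a <- la[cbind(seq_len(nrow(la)), d)]
  lev_b <- lb[cbind(seq_len(nrow(lb)), d)]
  a_is_worse <- lev_a > lev_b
  u_a <- u[pairs$state_a]
  u_b <- u[pairs$state_b]
  u_worse <- ifelse(a_is_worse, u_a, u_b)
  u_better <- ifelse(a_is_worse, u_b, u_a)
  viol <- if (strictness == "strict") u_worse >= u_better
          else u_worse > u_better
  list(n_pairs = nrow(pairs),
       n_violations = sum(viol),
       fraction_violating = mean(viol),
       strictness = strictness)
}

#' Leave-one-out out-of-sample validation
#'
#' For each held-out state, all valuations of that state are removed, the
#' model is refitted on the reduced data, and the omitted state's observed
#' mean is compared with its posterior prediction. The standardized
#' residual is `(observed - predicted) / predicted_sd`.
#'
#' @param data Adjusted valuation data.
#' @param spec An `"sf6d_model_spec"`.
#' @param config An `"sf6d_chain_config"` used for every refit.
#' @param states_to_omit Character vector of state codes to hold out, one
#'   refit each; when `NULL`, `n_omit` states are sampled without
#'   replacement from the states present (using `seed`).
#' @param n_omit,seed Used only when `states_to_omit` is `NULL`.
#' @return Data frame with one row per omitted state: `state_code`,
#'   `observed_mean`, `predicted_mean`, `predicted_sd`, `sr`; attribute
#'   `rmse` holds the RMSE of observed vs predicted means.
#' @export
loo_validation <- function(data, spec, config, states_to_omit = NULL,
                           n_omit = 10L, seed = 1L) {
  present <- unique(data$state_code)
  if (is.null(states_to_omit)) {
    states_to_omit <- with_seed(seed,
                                sample(present, min(n_omit,
                                                    length(present))))
  }
  missing_states <- setdiff(states_to_omit, present)
  if (length(missing_states) > 0) {
    stop("states not present in the data: ",
         paste(missing_states, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(states_to_omit, function(s) {
    keep <- data$state_code != s
    reduced <- data[keep, , drop = FALSE]
    left <- tapply(reduced$state_code, reduced$respondent_id,
                   function(x) length(unique(x)))
    if (any(left < 2)) {
      stop("omitting ", s, " leaves a respondent with fewer than 2 states",
           call. = FALSE)
    }
    fit <- run_mcmc(reduced, spec, config)
    pred <- predict_state_utility(fit, s)
    obs <- mean(data$y[data$state_code == s])
    data.frame(state_code = s,
               observed_mean = obs,
               predicted_mean = pred$predicted_mean,
               predicted_sd = pred$predicted_sd,
               sr = (obs - pred$predicted_mean) / pred$predicted_sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rmse") <- rmse(out$observed_mean, out$predicted_mean)
  out
}

#' Normal Q-Q coordinates for standardized residuals
#'
#' Pairs the sorted residuals with standard-normal quantiles at plotting
#' positions `(i - 0.5) / n`.
#'
#' @param standardized_residuals Numeric vector, length at least 2.
#' @return Data frame with columns `theoretical` and `empirical`.
#' @export
qq_points <- function(standardized_residuals) {
  n <- length(standardized_residuals)
  if (n < 2) stop("need at least 2 residuals", call. = FALSE)
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
             empirical = sort(standardized_residuals))
}
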