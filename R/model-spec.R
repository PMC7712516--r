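#' Specify one of the six model variants
#'
#' The candidate models cross two likelihood families with optional
#' respondent random intercepts and optional sociodemographic covariates:
#' linear regression (LR) with homoscedastic normal errors, and beta
#' regression (BR) with a logit link and precision parameter `phi`
#' (`Var(y) = mu * (1 - mu) / (1 + phi)`).
#'
#' Default priors are vague: `beta ~ N(0, 10^6)` on every regression
#' coefficient and `IG(0.001, 0.001)` on the residual variance (LR), the
#' random-intercept variance, and `phi` (BR). Two alternative priors are
#' available: `flat_sigma` replaces the inverse-gamma on the random-effect
#' variance with `p(sigma^2) proportional to 1/sigma`, and
#' `phi_uniform_squared` replaces the inverse-gamma on `phi` with the prior
#' induced by `phi = U^2`, `U ~ Uniform(0, a)`.
#'
#' @param family `"linear"` or `"beta"`.
#' @param random_effects Include per-respondent random intercepts?
#' @param covariates Include the nine covariate terms (AGE, GENDER, DEGREE,
#'   HOUSING1/2, INCOME1/2, MS1/2)?
#' @param prior_beta_variance Prior variance of each regression coefficient.
#' @param prior_ig_shape,prior_ig_rate Inverse-gamma hyperparameters shared
#'   by the variance/precision priors.
#' @param alt_priors Character vector, any of `"flat_sigma"`,
#'   `"phi_uniform_squared"`; empty for the defaults.
#' @param phi_uniform_bound Bound `a` of the `phi = U^2` alternative prior.
#' @return An object of class `"sf6d_model_spec"`.
#' @seealso [model_spec_from_name()] for the paper-style labels
#'   (`"BR+RE"` etc.), [run_mcmc()].
#' @export
model_spec <- function(family = c("beta", "linear"),
                       random_effects = FALSE,
                       covariates = FALSE,
                       prior_beta_variance = 1e6,
                       prior_ig_shape = 0.001,
                       prior_ig_rate = 0.001,
                       alt_priors = character(0),
                       phi_uniform_bound = 50) {
  family <- match.arg(family)
  stopifnot(prior_beta_variance > 0, prior_ig_shape > 0, prior_ig_rate > 0,
            phi_uniform_bound > 0)
  bad <- setdiff(alt_priors, c("flat_sigma", "phi_uniform_squared"))
  if (length(bad)) {
    stop("unknown alt_priors: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(family = family,
         random_effects = isTRUE(random_effects),
         covariates = isTRUE(covariates),
         prior_beta_variance = prior_beta_variance,
         prior_ig_shape = prior_ig_shape,
         prior_ig_rate = prior_ig_rate,
         alt_priors = alt_priors,
         phi_uniform_bound = phi_uniform_bound),
    class = "sf6d_model_spec"
  )
}

#' @export
print.sf6d_model_spec <- function(x, ...) {
  cat("SF-6D model:", model_name(x), "\n")
  cat("  family:", x$family,
      "| random effects:", x$random_effects,
      "| covariates:", x$covariates, "\n")
  if (length(x$alt_priors)) {
    cat("  alternative priors:", paste(x$alt_priors, collapse = ", "), "\n")
  }
  invisible(x)
}

.sf6d_model_names <- c("LR", "BR", "LR+RE", "BR+RE", "LR+RE+COV", "BR+RE+COV")

#' Model label of a specification
#' @param spec An `"sf6d_model_spec"`.
#' @return One of `"LR"`, `"BR"`, `"LR+RE"`, `"BR+RE"`, `"LR+RE+COV"`,
#'   `"BR+RE+COV"`.
#' @export
model_name <- function(spec) {
  paste0(if (spec$family == "linear") "LR" else "BR",
         if (spec$random_effects) "+RE" else "",
         if (spec$covariates) "+COV" else "")
}

#' Build a model specification from its label
#'
#' @param name One of the six model labels (`"LR"`, `"BR"`, `"LR+RE"`,
#'   `"BR+RE"`, `"LR+RE+COV"`, `"BR+RE+COV"`).
#' @param ... Passed on to [model_spec()] (priors etc.).
#' @return An `"sf6d_model_spec"`.
#' @export
model_spec_from_name <- function(name, ...) {
  if (!name %in% .sf6d_model_names) {
    stop("unknown model ", sQuote(name), "; valid names: ",
         paste(.sf6d_model_names, collapse = ", "), call. = FALSE)
  }
  parts <- strsplit(name, "+", fixed = TRUE)[[1]]
  model_spec(family = if (parts[1] == "LR") "linear" else "beta",
             random_effects = "RE" %in% parts,
             covariates = "COV" %in% parts,
             ...)
}

#' MCMC chain configuration
#'
#' Defaults follow the estimation protocol used throughout: two parallel
#' chains from spread initial values, 5000 burn-in iterations discarded,
#' 10,000 retained draws per chain. Proposal scales of the Metropolis blocks
#' adapt toward a 0.35 acceptance rate during burn-in only (Robbins-Monro),
#' so the retained draws come from a fixed transition kernel.
#'
#' @param n_chains Number of chains (at least 2 for the Gelman-Rubin
#'   diagnostic).
#' @param burn_in Discarded iterations per chain.
#' @param n_samples Retained iterations per chain.
#' @param seed Integer seed; chain `k` uses `seed + k - 1`.
#' @param target_acceptance Adaptation target for Metropolis blocks.
#' @param init_jitter_sd Standard deviation of the overdispersion jitter
#'   applied to chains 2, 3, ... at initialization (on the coefficient scale
#'   and on the log variance/precision scales).
#' @return An object of class `"sf6d_chain_config"`.
#' @export
chain_config <- function(n_chains = 2L,
                         burn_in = 5000L,
                         n_samples = 10000L,
                         seed = 1L,
                         target_acceptance = 0.35,
                         init_jitter_sd = 0.25) {
  stopifnot(n_chains >= 1L, burn_in >= 0L, n_samples >= 1L,
            target_acceptance > 0, target_acceptance < 1)
  structure(
    list(n_chains = as.integer(n_chains),
         burn_in = as.integer(burn_in),
         n_samples = as.integer(n_samples),
         seed = as.integer(seed),
         target_acceptance = target_acceptance,
         init_jitter_sd = init_jitter_sd),
    class = "sf6d_chain_config"
  )
}
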