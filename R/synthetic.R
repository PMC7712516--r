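#' Default true coefficients for the synthetic generator
#'
#' The published Lebanese SF-6D valuation study's posterior-mean BR+RE
#' coefficients (intercept plus 25 level dummies), so that synthetic
#' studies have realistic state mean utilities (about 0.33 at the pits up
#' to about 0.89 near full health).
#'
#' @return Named numeric vector of length 26.
#' @export
reference_true_beta <- function() {
  t1 <- reference_table1()
  stats::setNames(t1$brre_mean, t1$parameter)[c("(Intercept)",
                                                sf6d_dummy_names())]
}

#' Configuration of a synthetic valuation study
#'
#' The generator emulates the design of the Lebanese SF-6D study: 49 states
#' split into 7 blocks of 7, respondents assigned to blocks round-robin,
#' and every respondent additionally valuing the pits state, so each
#' respondent contributes 8 valuations. Utilities are drawn from the BR+RE
#' data-generating process: `y ~ Beta(mu * phi, (1 - mu) * phi)` with
#' `logit(mu) = x' beta + b_i`, `b_i ~ N(0, sigma_b^2)`.
#'
#' @param n_respondents Number of respondents (default 126, giving
#'   126 x 8 = 1008 valuations and 18 per non-pits state).
#' @param state_panel Character vector of 49 state codes (7 blocks of 7 in
#'   order); defaults to the published study's panel.
#' @param true_beta Named true coefficient vector (intercept + 25 dummies);
#'   defaults to the published BR+RE posterior means.
#' @param true_phi True beta precision (default 9.943, the published
#'   BR+RE posterior mean).
#' @param true_sigma_b True random-intercept SD on the logit scale
#'   (default 0.3).
#' @param covariate_effects Named vector of true covariate effects on the
#'   logit scale (default all zero, matching the published finding that no
#'   covariate interval excluded zero).
#' @param n_constant_respondents Number of respondents whose 8 values are
#'   overwritten with a single constant (default 0; set 2 to mimic the
#'   study's two excluded respondents).
#' @param boundary_eps Redraw utilities within this distance of 0 or 1.
#' @param seed Integer seed.
#' @return An object of class `"sf6d_generator_config"`.
#' @export
generator_config <- function(n_respondents = 126L,
                             state_panel = NULL,
                             true_beta = NULL,
                             true_phi = 9.943,
                             true_sigma_b = 0.3,
                             covariate_effects = NULL,
                             n_constant_respondents = 0L,
                             boundary_eps = 1e-6,
                             seed = 1L) {
  if (is.null(state_panel)) {
    state_panel <- setdiff(reference_table2()$state_code, "645655")
  }
  if (length(state_panel) %% 7L != 0L) {
    stop("state_panel must split into blocks of 7", call. = FALSE)
  }
  invisible(lapply(state_panel, parse_state_code))  # validate codes
  if (is.null(true_beta)) true_beta <- reference_true_beta()
  need <- c("(Intercept)", sf6d_dummy_names())
  if (!all(need %in% names(true_beta))) {
    stop("true_beta must be named: intercept + 25 dummies", call. = FALSE)
  }
  if (true_phi <= 0 || true_sigma_b < 0) {
    stop("true_phi must be positive and true_sigma_b non-negative",
         call. = FALSE)
  }
  if (is.null(covariate_effects)) {
    covariate_effects <- stats::setNames(numeric(9), covariate_names())
  }
  structure(
    list(n_respondents = as.integer(n_respondents),
         state_panel = state_panel,
         n_blocks = length(state_panel) %/% 7L,
         true_beta = true_beta[need],
         true_phi = true_phi,
         true_sigma_b = true_sigma_b,
         covariate_effects = covariate_effects[covariate_names()],
         n_constant_respondents = as.integer(n_constant_respondents),
         boundary_eps = boundary_eps,
         seed = as.integer(seed)),
    class = "sf6d_generator_config"
  )
}

#' Generate a synthetic valuation study
#'
#' Respondents are assigned round-robin to the blocks of the state panel
#' and receive their block's 7 states plus the pits. Per respondent,
#' `b_i ~ N(0, sigma_b^2)`; per record, `mu = inverse-logit(x' beta + b_i +
#' covariate effects)` and `y ~ Beta(mu * phi, (1 - mu) * phi)`, redrawn
#' while within `boundary_eps` of 0 or 1 so the likelihood stays exactly
#' beta. Covariates: age uniform on 18-65 (integer years), gender and
#' degree Bernoulli(0.5), housing/income/marital status uniform over three
#' categories. Optionally the first `n_constant_respondents` respondents'
#' 8 values are overwritten with their own pits draw, creating
#' "flat-liners" for the exclusion filter.
#'
#' @param config An `"sf6d_generator_config"`.
#' @return An object of class `"sf6d_study"`: `valuations` (respondent_id,
#'   state_code, y, is_pits, mu_true, block), `respondents` (profiles),
#'   `truth` (true beta, phi, sigma_b, covariate effects, per-respondent
#'   b), `config`.
#' @export
generate_study <- function(config = generator_config()) {
  stopifnot(inherits(config, "sf6d_generator_config"))
  with_seed(config$seed, {
    nr <- config$n_respondents
    nb <- config$n_blocks
    blocks <- split(config$state_panel,
                    rep(seq_len(nb), each = 7L))
    ids <- sprintf("R%03d", seq_len(nr))
    block_of <- ((seq_len(nr) - 1L) %% nb) + 1L

    respondents <- data.frame(
      respondent_id = ids,
      age = sample(18:65, nr, replace = TRUE),
      gender = sample(0:1, nr, replace = TRUE),
      degree = sample(0:1, nr, replace = TRUE),
      housing = sample(1:3, nr, replace = TRUE),
      income = sample(1:3, nr, replace = TRUE),
      marital_status = sample(1:3, nr, replace = TRUE),
      stringsAsFactors = FALSE
    )
    b <- stats::rnorm(nr, 0, config$true_sigma_b)

    states_of <- lapply(block_of, function(k) c(blocks[[k]], "645655"))
    val <- data.frame(
      respondent_id = rep(ids, each = 8L),
      state_code = unlist(states_of),
      is_pits = rep(c(rep(FALSE, 7L), TRUE), nr),
      block = rep(block_of, each = 8L),
      stringsAsFactors = FALSE
    )
    X <- cbind(`(Intercept)` = 1, design_matrix(val$state_code))
    cov_eta <- drop(covariate_matrix(
      respondents[match(val$respondent_id, respondents$respondent_id), ]
    ) %*% config$covariate_effects)
    eta <- drop(X %*% config$true_beta) +
      b[match(val$respondent_id, ids)] + cov_eta
    mu <- stats::plogis(eta)
    y <- draw_beta_interior(mu, config$true_phi, config$boundary_eps)

    if (config$n_constant_respondents > 0L) {
      const_ids <- ids[seq_len(config$n_constant_respondents)]
      for (id in const_ids) {
        rows <- val$respondent_id == id
        y[rows] <- y[rows & val$is_pits]
      }
    }
    val$y <- y
    val$mu_true <- mu

    structure(
      list(valuations = val,
           respondents = respondents,
           truth = list(beta = config$true_beta,
                        phi = config$true_phi,
                        sigma_b = config$true_sigma_b,
                        covariate_effects = config$covariate_effects,
                        b = stats::setNames(b, ids)),
           config = config),
      class = "sf6d_study"
    )
  })
}

# Beta draws with boundary redraws, keeping the likelihood exactly beta.
draw_beta_interior <- function(mu, phi, eps) {
  y <- stats::rbeta(length(mu), mu * phi, (1 - mu) * phi)
  bad <- y < eps | y > 1 - eps
  while (any(bad)) {
    y[bad] <- stats::rbeta(sum(bad), mu[bad] * phi, (1 - mu[bad]) * phi)
    bad <- y < eps | y > 1 - eps
  }
  y
}

#' Raw standard-gamble responses implied by a synthetic study
#'
#' Inverts the SG adjustment so the preprocessing pipeline reconstructs the
#' generated utilities exactly: the pits task carries `P = y_pits` and each
#' non-pits task carries `SG = (y - P) / (1 - P)`.
#'
#' @param study An `"sf6d_study"`.
#' @return Data frame with columns `respondent_id`, `state_code`, `sg`,
#'   `is_pits` — the input schema of [build_dataset()].
#' @export
generate_raw_sg_layer <- function(study) {
  stopifnot(inherits(study, "sf6d_study"))
  val <- study$valuations
  pits <- val$y[val$is_pits]
  names(pits) <- val$respondent_id[val$is_pits]
  if (any(pits >= 1)) stop("pits valuation of 1 cannot be inverted",
                           call. = FALSE)
  p_of <- pits[val$respondent_id]
  sg <- ifelse(val$is_pits, val$y, (val$y - p_of) / (1 - p_of))
  data.frame(respondent_id = val$respondent_id,
             state_code = val$state_code,
             sg = as.numeric(sg),
             is_pits = val$is_pits,
             stringsAsFactors = FALSE)
}

#' Parameter-recovery experiment for the BR+RE model
#'
#' Repeatedly generates a synthetic study, runs it through the
#' preprocessing pipeline, fits the specified model, and records, for each
#' true regression coefficient, whether it lies inside its 95% credible
#' interval and the posterior-mean error.
#'
#' @param n_replicates Number of replicate studies.
#' @param config An `"sf6d_generator_config"`; replicate `r` uses
#'   `config$seed + r - 1` for generation and fitting.
#' @param fit_config An `"sf6d_chain_config"` for the fits.
#' @param spec Model to fit (default BR+RE).
#' @return List with `per_parameter` (data frame: parameter, coverage,
#'   mean bias), `pooled_coverage` over the 25 dummy coefficients,
#'   `max_rhat` per replicate, `n_failed` (replicates whose fit errored).
#' @export
parameter_recovery_experiment <- function(n_replicates, config,
                                          fit_config,
                                          spec = model_spec(
                                            "beta", random_effects = TRUE)) {
  stopifnot(n_replicates >= 1)
  dummies <- sf6d_dummy_names()
  truth <- config$true_beta
  cover <- bias <- matrix(NA_real_, n_replicates, length(truth),
                          dimnames = list(NULL, names(truth)))
  max_rhat <- rep(NA_real_, n_replicates)
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    fcfg <- fit_config
    fcfg$seed <- fit_config$seed + r - 1L
    res <- tryCatch({
      study <- generate_study(cfg)
      raw <- generate_raw_sg_layer(study)
      dat <- build_dataset(raw, study$respondents)
      dat <- filter_constant_respondents(dat)$data
      fit <- run_mcmc(dat, spec, fcfg)
      sm <- summarize_posterior(fit, params = names(truth))
      list(sm = sm, rhat = max(gelman_rubin(fit)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    sm <- res$sm
    idx <- match(names(truth), sm$parameter)
    cover[r, ] <- truth >= sm$lower[idx] & truth <= sm$upper[idx]
    bias[r, ] <- sm$mean[idx] - truth
    max_rhat[r] <- res$rhat
  }
  per_parameter <- data.frame(
    parameter = names(truth),
    coverage = colMeans(cover, na.rm = TRUE),
    mean_bias = colMeans(bias, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  rownames(per_parameter) <- NULL
  list(per_parameter = per_parameter,
       pooled_coverage = mean(cover[, dummies], na.rm = TRUE),
       max_rhat = max_rhat,
       n_failed = n_failed)
}
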