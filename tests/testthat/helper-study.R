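# Small synthetic studies and short chain configurations shared by tests.

small_study <- function(n_respondents = 28L, seed = 1L, ...) {
  generate_study(generator_config(n_respondents = n_respondents,
                                  seed = seed, ...))
}

small_dataset <- function(n_respondents = 28L, seed = 1L, ...) {
  study <- small_study(n_respondents, seed, ...)
  build_dataset(generate_raw_sg_layer(study), study$respondents)
}

fast_config <- function(seed = 1L, burn_in = 300L, n_samples = 600L) {
  chain_config(n_chains = 2L, burn_in = burn_in, n_samples = n_samples,
               seed = seed)
}

# Minimal hand-built fit object (point-mass draws) for degenerate-input
# tests of summarize/predict/dic.
constant_fit <- function(values, data, spec = model_spec("beta"),
                         n_draws = 20L) {
  mf <- sf6dbayes:::build_model_frame(data, spec)
  nm <- sf6dbayes:::param_layout(mf, spec)
  stopifnot(setequal(names(values), nm))
  draws <- matrix(rep(values[nm], each = n_draws), nrow = n_draws,
                  dimnames = list(NULL, nm))
  b_of <- if (spec$random_effects) {
    values[paste0("b[", mf$resp_ids, "]")][mf$resp]
  } else 0
  eta <- drop(mf$X %*% values[colnames(mf$X)]) + b_of
  dev <- if (spec$family == "beta") {
    -2 * sum(beta_log_density(mf$y, plogis(eta), values[["phi"]]))
  } else {
    -2 * sum(dnorm(mf$y, eta, sqrt(values[["sigma2_eps"]]), log = TRUE))
  }
  structure(
    list(spec = spec, config = chain_config(seed = 1L),
         param_names = nm,
         chains = list(draws, draws),
         deviance = list(rep(dev, n_draws), rep(dev, n_draws)),
         acceptance = list(), mf = mf),
    class = "sf6d_fit"
  )
}
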