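#' Reproducible analysis pipeline
#'
#' Thin wrappers tying the stages together through files on disk, so a full
#' simulate -> fit -> evaluate -> audit -> loo run is scriptable and
#' repeatable: every stochastic step takes an explicit seed and fixed seeds
#' give byte-identical artifacts. Tabular artifacts are UTF-8 CSV with a
#' header row; summaries are JSON.
#'
#' @name pipeline
NULL

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Simulate a study to disk
#'
#' Writes `valuations.csv` (respondent_id, state_code, sg, is_pits),
#' `respondents.csv` (profiles) and `truth.json` (true parameters and the
#' generator seed) under `out_dir`.
#'
#' @param config An `"sf6d_generator_config"`.
#' @param out_dir Output directory (created if needed; must be writable).
#' @return Invisibly, the generated `"sf6d_study"`.
#' @rdname pipeline
#' @export
pipeline_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  study <- generate_study(config)
  raw <- generate_raw_sg_layer(study)
  raw$is_pits <- as.integer(raw$is_pits)
  utils::write.csv(raw, file.path(out_dir, "valuations.csv"),
                   row.names = FALSE)
  utils::write.csv(study$respondents,
                   file.path(out_dir, "respondents.csv"), row.names = FALSE)
  write_json_file(
    list(seed = config$seed,
         n_respondents = config$n_respondents,
         true_phi = study$truth$phi,
         true_sigma_b = study$truth$sigma_b,
         true_beta = as.list(study$truth$beta)),
    file.path(out_dir, "truth.json")
  )
  invisible(study)
}

#' Read a simulated (or real) study from disk and preprocess it
#'
#' Reads `valuations.csv` and `respondents.csv` from `dir`, assembles
#' adjusted utilities and applies the constant-respondent filter.
#'
#' @param dir Directory holding the two CSVs.
#' @param adjusted_file Optional path; when given, the filtered adjusted
#'   dataset is also written there as CSV (`adjusted.csv` schema, with the
#'   `y` column).
#' @return The filtered adjusted dataset (see [build_dataset()]).
#' @rdname pipeline
#' @export
pipeline_read_data <- function(dir, adjusted_file = NULL) {
  raw <- utils::read.csv(file.path(dir, "valuations.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(state_code = "character"))
  profiles <- utils::read.csv(file.path(dir, "respondents.csv"),
                              stringsAsFactors = FALSE)
  dat <- build_dataset(raw, profiles)
  dat <- filter_constant_respondents(dat)$data
  if (!is.null(adjusted_file)) {
    utils::write.csv(dat, adjusted_file, row.names = FALSE)
  }
  dat
}

#' Fit one named model and persist the results
#'
#' Fits one of the six models (`"LR"`, `"BR"`, `"LR+RE"`, `"BR+RE"`,
#' `"LR+RE+COV"`, `"BR+RE+COV"`) and writes `summary_<model>.json`
#' (posterior summaries, R-hat, acceptance rates, DIC) and
#' `draws_<model>.csv` (pooled retained draws, one column per parameter).
#' Emits a warning (non-fatal) when any R-hat is 1.1 or above.
#'
#' @param data Adjusted valuation data.
#' @param model_name One of the six model labels.
#' @param config An `"sf6d_chain_config"`.
#' @param out_dir Output directory.
#' @return Invisibly, the `"sf6d_fit"`.
#' @rdname pipeline
#' @export
pipeline_fit <- function(data, model_name, config, out_dir) {
  spec <- model_spec_from_name(model_name)
  fit <- run_mcmc(data, spec, config)
  rhat <- gelman_rubin(fit)
  if (any(rhat >= 1.1)) {
    warning(sprintf("convergence warning for %s: max Rhat = %.3f",
                    model_name, max(rhat)), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sm <- summarize_posterior(fit)
  tag <- gsub("+", "_", model_name, fixed = TRUE)
  write_json_file(
    list(model = model_name,
         summary = sm,
         max_rhat = max(rhat),
         acceptance = lapply(fit$acceptance, as.list),
         dic = attr(sm, "dic")),
    file.path(out_dir, paste0("summary_", tag, ".json"))
  )
  utils::write.csv(do.call(rbind, fit$chains),
                   file.path(out_dir, paste0("draws_", tag, ".csv")),
                   row.names = FALSE)
  message(sprintf("%s: DIC = %.1f (Dbar %.1f, pD %.1f), max Rhat %.3f",
                  model_name, attr(sm, "dic")$DIC, attr(sm, "dic")$Dbar,
                  attr(sm, "dic")$pD, max(rhat)))
  invisible(fit)
}

#' Side-by-side evaluation of fitted models
#'
#' Writes `metrics.json` (MPE/RMSE/DIC per model at the requested
#' aggregation level) and `predictions_<model>.csv` (state, observed,
#' predicted, sd).
#'
#' @param fits Named list of `"sf6d_fit"` objects.
#' @param data The adjusted data the models were fitted to.
#' @param out_dir Output directory.
#' @param aggregation `"state_mean"` or `"record"`.
#' @return Invisibly, the metrics list.
#' @rdname pipeline
#' @export
pipeline_evaluate <- function(fits, data, out_dir,
                              aggregation = "state_mean") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- lapply(fits, evaluation_metrics, data = data,
                    aggregation = aggregation)
  write_json_file(metrics, file.path(out_dir, "metrics.json"))
  for (nm in names(fits)) {
    tab <- prediction_table(fits[[nm]], data)
    tag <- gsub("+", "_", nm, fixed = TRUE)
    utils::write.csv(tab,
                     file.path(out_dir, paste0("predictions_", tag,
                                               ".csv")),
                     row.names = FALSE)
  }
  invisible(metrics)
}

#' Monotonicity audit to disk
#'
#' Samples `n_pairs` adjacent pairs (reproducibly from `seed`) and writes
#' `monotonicity.json` with the violation fraction per supplied fit.
#'
#' @param fits Named list of fits (or coefficient vectors).
#' @param n_pairs Number of adjacent pairs.
#' @param seed Pair-sampling seed.
#' @param out_dir Output directory.
#' @param strictness Passed to [monotonicity_audit()].
#' @return Invisibly, the list of audit reports.
#' @rdname pipeline
#' @export
pipeline_audit <- function(fits, n_pairs, seed, out_dir,
                           strictness = "non_strict") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pairs <- sample_adjacent_pairs(n_pairs, seed = seed)
  reports <- lapply(fits, monotonicity_audit, pairs = pairs,
                    strictness = strictness)
  write_json_file(reports, file.path(out_dir, "monotonicity.json"))
  invisible(reports)
}

#' Leave-one-out validation to disk
#'
#' Writes `loo_<model>.csv` (omitted state, observed mean, predicted mean
#' and SD, standardized residual) per model and returns the results.
#'
#' @param data Adjusted valuation data.
#' @param model_names Character vector of model labels to validate.
#' @param config Chain configuration for the refits.
#' @param states_to_omit,n_omit,seed Passed to [loo_validation()].
#' @param out_dir Output directory.
#' @return Invisibly, named list of LOO tables.
#' @rdname pipeline
#' @export
pipeline_loo <- function(data, model_names, config, out_dir,
                         states_to_omit = NULL, n_omit = 10L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- lapply(model_names, function(nm) {
    res <- loo_validation(data, model_spec_from_name(nm), config,
                          states_to_omit = states_to_omit,
                          n_omit = n_omit, seed = seed)
    tag <- gsub("+", "_", nm, fixed = TRUE)
    utils::write.csv(res, file.path(out_dir, paste0("loo_", tag, ".csv")),
                     row.names = FALSE)
    res
  })
  names(out) <- model_names
  invisible(out)
}
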