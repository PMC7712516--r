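#' Gelman-Rubin potential scale reduction factors
#'
#' Compares between-chain and within-chain variance per scalar parameter
#' over the retained draws; values near 1 indicate convergence. A parameter
#' that is constant across all chains is reported as exactly 1 by
#' convention.
#'
#' @param fit An `"sf6d_fit"`, or a list of draw matrices (equal
#'   dimensions, one column per parameter).
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(fit) {
  chains <- if (inherits(fit, "sf6d_fit")) fit$chains else fit
  if (length(chains) < 2) {
    stop("Gelman-Rubin diagnostic needs at least 2 chains", call. = FALSE)
  }
  n <- nrow(chains[[1]])
  if (n < 10) stop("need at least 10 draws per chain", call. = FALSE)
  means <- sapply(chains, colMeans)                      # p x k
  vars <- sapply(chains, function(ch) apply(ch, 2, stats::var))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  W <- rowMeans(vars)
  B <- n * apply(means, 1, stats::var)
  var_plus <- (n - 1) / n * W + B / n
  rhat <- sqrt(var_plus / W)
  rhat[W == 0] <- 1
  stats::setNames(rhat, colnames(chains[[1]]))
}

#' Posterior summary of a fitted model
#'
#' Pools the retained draws of all chains and reports, per scalar
#' parameter, the posterior mean, standard deviation, equal-tailed 95%
#' credible interval (2.5% and 97.5% percentiles), the Gelman-Rubin R-hat,
#' and whether the interval excludes zero (the criterion used to flag
#' influential coefficients).
#'
#' @param fit An `"sf6d_fit"`.
#' @param params Optional character vector restricting the summary to some
#'   parameters (default: all).
#' @return A data frame of class `"sf6d_fit_summary"` with columns
#'   `parameter`, `mean`, `sd`, `lower`, `upper`, `rhat`, `excl_zero`, and
#'   attributes `model` and `dic` (the [dic()] components).
#' @export
summarize_posterior <- function(fit, params = NULL) {
  stopifnot(inherits(fit, "sf6d_fit"))
  pooled <- do.call(rbind, fit$chains)
  if (!is.null(params)) pooled <- pooled[, params, drop = FALSE]
  qs <- apply(pooled, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  out <- data.frame(
    parameter = colnames(pooled),
    mean = colMeans(pooled),
    sd = apply(pooled, 2, stats::sd),
    lower = qs[1, ],
    upper = qs[2, ],
    rhat = if (length(fit$chains) >= 2) {
      gelman_rubin(fit)[colnames(pooled)]
    } else NA_real_,
    stringsAsFactors = FALSE
  )
  out$excl_zero <- out$lower > 0 | out$upper < 0
  rownames(out) <- NULL
  attr(out, "model") <- model_name(fit$spec)
  attr(out, "dic") <- dic(fit)
  class(out) <- c("sf6d_fit_summary", "data.frame")
  out
}

#' @export
print.sf6d_fit_summary <- function(x, ...) {
  cat("Posterior summary,", attr(x, "model"), "model\n")
  y <- as.data.frame(x)
  if (!is.null(y$excl_zero)) y$excl_zero <- ifelse(y$excl_zero, "*", "")
  print.data.frame(y, digits = 3, row.names = FALSE)
  d <- attr(x, "dic")
  if (!is.null(d)) {
    cat(sprintf("Dbar = %.1f, pD = %.1f, DIC = %.1f\n",
                d$Dbar, d$pD, d$DIC))
  }
  invisible(x)
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD`, where `Dbar` is the posterior mean of the conditional
#' deviance `-2 log L` (conditional on the random effects for RE models)
#' and `pD = Dbar - D(theta_hat)` is the effective number of parameters,
#' with `theta_hat` the posterior mean of all sampled parameters. Lower is
#' better.
#'
#' @param fit An `"sf6d_fit"`.
#' @return List with `Dbar`, `pD`, `DIC`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "sf6d_fit"))
  Dbar <- mean(unlist(fit$deviance))
  pooled <- do.call(rbind, fit$chains)
  est <- colMeans(pooled)
  mf <- fit$mf
  spec <- fit$spec
  beta_hat <- est[colnames(mf$X)]
  b_hat <- if (spec$random_effects) {
    est[paste0("b[", mf$resp_ids, "]")][mf$resp]
  } else 0
  eta <- drop(mf$X %*% beta_hat) + b_hat
  Dhat <- if (spec$family == "beta") {
    -2 * sum(beta_log_density(mf$y, stats::plogis(eta), est[["phi"]]))
  } else {
    -2 * sum(stats::dnorm(mf$y, eta, sqrt(est[["sigma2_eps"]]), log = TRUE))
  }
  if (!is.finite(Dhat)) stop("non-finite deviance at the posterior mean",
                             call. = FALSE)
  pD <- Dbar - Dhat
  list(Dbar = Dbar, pD = pD, DIC = Dbar + pD)
}

# Monte-Carlo standard error of a chain mean by non-overlapping batch means.
mcse_mean <- function(x, n_batches = 30L) {
  n <- length(x)
  bs <- floor(n / n_batches)
  bm <- colMeans(matrix(x[seq_len(bs * n_batches)], nrow = bs))
  stats::sd(bm) / sqrt(n_batches)
}
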