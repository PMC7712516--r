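---
title: "Bayesian beta and linear regression for SF-6D standard-gamble valuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian beta and linear regression for SF-6D standard-gamble valuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sf6dbayes)
```

## The problem

Preference-based health measures such as the SF-6D define far more health
states (18,000) than any valuation survey can elicit directly. A valuation
study therefore measures utilities for a sample of states — here, 49 states
plus the worst state ("the pits", code 645655), each respondent valuing a
block of 7 states and the pits by standard gamble — and a regression model
interpolates the remaining states from dummy variables for each
dimension level above 1.

Standard-gamble utilities live on the death = 0 / full health = 1 scale,
are bounded above by 1, left-skewed, and heteroscedastic (their variance
shrinks near the boundary). Ordinary linear regression ignores all of
that, which motivates a beta-likelihood alternative. `sf6dbayes`
implements both families and the machinery to compare them.

## Preprocessing

Each respondent's pits valuation $P$ (bounded below at $-1$; values below
$-1$ mean "worse than death" and are truncated) anchors their other seven
responses via

$$\mathrm{SG}_{adj} = \mathrm{SG} + (1 - \mathrm{SG})\,P .$$

The pits task itself enters the dataset with $y = P$, so the pits behaves
like any other state when summarizing or fitting; the published per-state
table treats it the same way. Respondents whose eight values are all
identical carry no preference information and are excluded in full
(exact equality by default; a tolerance knob exists for floating-point
fixtures). With 126 respondents and two such "flat-liners" this retains
992 of 1008 records (98.4%). The filter runs on adjusted values; running
it on raw values would flag the same respondents except in contrived
cases, and adjusted values are what the models see.

Utilities of 0 or 1 are legal in preprocessing output — the linear family
can use them — but the beta likelihood requires $0 < y < 1$ and the fit
errors by default. `compress_boundary()` implements the usual
$y' = (y(n-1) + 0.5)/n$ compression as an explicit opt-in; the study data
this design mirrors contained no boundary values.

## The six models

With $x_i$ the 25 level dummies (plus, optionally, nine covariate terms:
age in years, and reference-coded dummies for gender, degree, housing,
income and marital status):

* **LR**: $y_i = x_i^T\beta + \varepsilon_i$,
  $\varepsilon_i \sim N(0, \sigma_2^2)$.
* **BR**: $y_i \sim \mathrm{Beta}(\mu_i\phi, (1-\mu_i)\phi)$ with
  $\mathrm{logit}(\mu_i) = x_i^T\beta$, so $E(y_i) = \mu_i$ and
  $\mathrm{Var}(y_i) = \mu_i(1-\mu_i)/(1+\phi)$ — bounded support and
  mean-dependent variance for free.
* **+RE**: a respondent intercept $b_j \sim N(0, \sigma_1^2)$ added to the
  linear predictor *before* the logit in the beta family, capturing
  consistently high or low valuers.
* **+COV**: the nine covariate terms appended to $x_i$.

Priors are deliberately vague: $\beta_k \sim N(0, 10^6)$ and
$\sigma_1^2, \sigma_2^2, \phi \sim IG(0.001, 0.001)$. Two alternatives are
available as options: a flat prior on $\sigma_1$
($p(\sigma_1^2) \propto 1/\sigma_1$), and the prior induced on $\phi$ by
$\phi = U^2$, $U \sim \mathrm{Uniform}(0, a)$ with $a = 50$ by default.
No truncation is imposed on $\phi$ under the default prior.

## Estimation

`run_mcmc()` follows a fixed protocol: two parallel chains from
overdispersed starts, 5000 burn-in iterations discarded, 10,000 retained
draws per chain (all configurable). Convergence is monitored by the
Gelman–Rubin statistic; any $\hat R \ge 1.1$ triggers a warning in the
pipeline wrapper.

The updates are Metropolis-within-Gibbs:

* Linear family: fully conjugate Gibbs — $\beta \mid \sigma_2^2$
  multivariate normal, $\sigma_2^2 \mid \beta$ inverse gamma, each
  $b_j \mid \cdot$ normal, $\sigma_1^2 \mid b$ inverse gamma.
* Beta family: $\beta$ by an adaptive Gaussian random-walk block move
  *plus* a per-coordinate scan (two sweeps) that exploits the sparsity of
  the dummy design — a scalar move on one dummy only touches the records
  of the few states that activate it, so the scan costs little and mixes
  the coefficients far better than the block move alone; $\phi$ by a
  random walk on $\log\phi$ (Jacobian included); each $b_j$ by scalar
  random walk, vectorized over respondents; $\sigma_1^2 \mid b$ by Gibbs.

All proposal scales adapt by Robbins–Monro toward a 0.35 acceptance rate
during burn-in only, so retained draws come from a fixed kernel. The
block proposal covariance starts at $(X^TX)^{-1}$ — which already encodes
the intercept–dummy correlation structure — and switches to a running
estimate of the posterior covariance (scaled by $2.38^2/d$) once enough
burn-in draws have accumulated.

Two further choices matter in practice and were adopted after the plain
block sampler proved too slowly-mixing at short chain lengths:

* **Initialization** at the least-squares solution on the (logit-scale)
  response rather than at zero; chains beyond the first add $N(0, 0.25)$
  jitter to every coefficient (and twice that on the log variance and
  log precision scales). This is overdispersed relative to posterior
  spreads (roughly 0.03–0.08 here) while staying in a region the sampler
  can leave quickly.
* An **interweaving translation move**
  $(\beta_0, b) \to (\beta_0 + \delta,\, b - \delta)$, whose conditional
  for $\delta$ is normal in closed form and whose likelihood term is
  invariant. Without it the intercept and the random-effect mean form a
  slowly-mixing ridge (observed $\hat R$ up to 5 at short runs); with it
  the intercept mixes like any other coordinate. The same move is applied
  inside the linear-family Gibbs sweep.

Degenerate inputs are tolerated where statistically meaningful: a
respondent with a single record simply gets a prior-dominated $b_j$; a
proposal that pushes $\mu$ to the numerical boundary gets likelihood
$-\infty$ and is rejected.

## Model comparison and validation

* **MPE / RMSE.** RMSE is the root-mean-square error between observed and
  predicted values. "Mean prediction error" is implemented as mean
  absolute error; published usage is inconsistent about both its
  definition and its aggregation level, and the two aggregation levels
  (record-level residuals vs 49-state mean residuals) give very different
  magnitudes, so `evaluation_metrics()` takes the level as an explicit
  argument and defaults to state means — the level at which the
  in-sample RMSE figures 0.053/0.059 reproduce from the shipped reference
  table.
* **DIC** uses the conditional deviance (given the random effects) with
  $p_D = \bar D - D(\hat\theta)$ at the posterior mean of the sampled
  parameters — the convention of the WinBUGS era this analysis style
  comes from. On fixed-effects linear fits $p_D$ lands within a couple of
  units of the sampled-parameter count, a useful calibration check.
* **Predicted state utilities** use the plug-in convention $b = 0$ (the
  median respondent); a Monte-Carlo marginal version (averaging over
  $b \sim N(0, \sigma_1^2)$ within each draw) is available behind a flag.
  Plug-in reproduces the magnitude of the published per-state predictions
  (e.g. pits at 0.331 from the published coefficient means).
* **Monotonicity.** Utility should not rise when a single dimension
  worsens one level. The audit samples first states without replacement
  from all 18,000 (the same unordered pair can recur via different first
  elements — harmless for a rate estimate), picks one neighbor uniformly,
  and counts violations using plug-in utilities at the posterior-mean
  coefficients. Adjacency means "one dimension, one level": the printed
  6–12 neighbor range forces this reading, since allowing any level gap
  would give every state 25 neighbors. Ties are not violations by
  default (`non_strict`) because 3-decimal rounding of published
  coefficients creates spurious ties; `strict` mode counts them.
* **Leave-one-out validation** removes all valuations of one state,
  refits, and standardizes the prediction error by the posterior
  predictive SD of the state mean. Q–Q coordinates of those standardized
  residuals against normal quantiles at $(i - 0.5)/n$ are provided for
  plotting.

## The synthetic generator

No raw valuations from the study are publicly deposited, so the package
carries a generator that emulates the study design end-to-end: 49 panel
states in 7 blocks of 7 (the published panel by default), round-robin
block assignment (18 valuations per state at 126 respondents, matching
the published 17–18 up to their uneven recruitment; the allocation that
produced 17s is not published, so blocks are balanced), every respondent
valuing the pits, and utilities drawn from the BR+RE data-generating
process with the published posterior means as true coefficients
($\phi = 9.943$). The respondent SD on the logit scale defaults to
$\sigma_b = 0.3$, a moderate heterogeneity consistent with the spread the
published per-state SDs imply; it is configurable, as no value was
published. Covariates are drawn uniformly (age 18–65 in integer years,
binary and three-category variables equiprobable) with all true effects
zero, matching the published finding that every covariate interval
contained zero. Boundary values are redrawn rather than truncated so the
likelihood stays exactly beta. A raw-SG layer is synthesized by algebraic
inversion of the adjustment formula, so the preprocessing pipeline can be
exercised end-to-end with exact round-trips; the ping-pong elicitation
procedure itself is not simulated, and neither are behavioural artifacts
(probability-grid rounding, framing), so passing tests demonstrate
correctness of the machinery under the model's own assumptions, not
robustness to real-respondent behaviour.

## Problem sizes used by the tests

The test suite and the acceptance script run the full protocol at reduced
size: recovery experiments use 20 replicate studies of 126 × 8
valuations fitted with 2 chains × (1000 burn-in + 2000 draws), a scale at
which one BR+RE fit takes tens of seconds and the whole experiment
minutes, while leaving the Gelman–Rubin and coverage checks meaningful.
Unit tests use smaller panels (14–56 respondents) and shorter chains.
These sizes are the package's own choice of a meaningful-but-quick
default; the fitting functions default to the full 5000 + 10,000
protocol.

## Known limitations

* MPE's published values cannot be reproduced under any single
  definition tried; the package states its definition (MAE) and moves on.
* The published 15%/10% non-monotonicity rates depend on unpublished
  details (posterior draws vs means, tie handling) and are not asserted;
  the audit machinery itself is tested against constructed predictors.
* The beta family cannot represent utilities at or below 0 (worse than
  death); the study design bounds the pits at $-1$ but its data happened
  to contain no non-positive adjusted values. Datasets with them need
  the linear family or explicit boundary compression.
* One-dimensional $\hat R$ on every scalar parameter is the only
  convergence diagnostic; at the default protocol this matches the
  analysis style the package reproduces.
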