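#' Bound worse-than-death valuations at -1
#'
#' Standard-gamble valuations of the pits state may be negative (worse than
#' death); any negative value is bounded below at -1.
#'
#' @param v Numeric vector of raw valuations, each at most 1.
#' @return `pmax(v, -1)`.
#' @export
bound_negative <- function(v) {
  stopifnot(is.numeric(v))
  if (any(v > 1, na.rm = TRUE)) {
    stop("raw valuations cannot exceed 1", call. = FALSE)
  }
  pmax(v, -1)
}

#' Adjust a standard-gamble value onto the death = 0, full health = 1 scale
#'
#' Intermediate states are valued against full health and the pits; the
#' chained utility on the death/full-health scale is
#' `SGADJ = SG + (1 - SG) * P`, where `P` is the respondent's own (bounded)
#' valuation of the pits state.
#'
#' @param sg Raw SG indifference probability for a non-pits state (<= 1).
#' @param p The respondent's pits valuation, in `[-1, 1]`.
#' @return Adjusted utility `sg + (1 - sg) * p`.
#' @examples
#' adjust_sg(0.8, 0.5)  # 0.9
#' @export
adjust_sg <- function(sg, p) {
  stopifnot(is.numeric(sg), is.numeric(p))
  if (any(sg > 1, na.rm = TRUE)) stop("`sg` cannot exceed 1", call. = FALSE)
  if (any(p > 1 | p < -1, na.rm = TRUE)) {
    stop("`p` must lie in [-1, 1]", call. = FALSE)
  }
  sg + (1 - sg) * p
}

#' Assemble adjusted valuations from raw SG responses
#'
#' Each respondent values seven states from their block plus the pits state
#' (the eighth task). The pits response is bounded at -1 and used both as
#' that respondent's anchor `P` and as the pits record's own utility; every
#' non-pits response is rescaled with [adjust_sg()].
#'
#' @param raw Data frame with columns `respondent_id`, `state_code`, `sg`,
#'   `is_pits` (0/1 or logical).
#' @param profiles Optional data frame of respondent covariates with columns
#'   `respondent_id`, `age`, `gender`, `degree`, `housing`, `income`,
#'   `marital_status`; joined onto the output when supplied.
#' @return Data frame with columns `respondent_id`, `state_code`, `y`,
#'   `is_pits`, plus covariates when `profiles` is given. One row per input
#'   row.
#' @export
build_dataset <- function(raw, profiles = NULL) {
  need <- c("respondent_id", "state_code", "sg", "is_pits")
  if (!all(need %in% names(raw))) {
    stop("`raw` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  raw$is_pits <- as.logical(raw$is_pits)
  pits_per_resp <- tapply(raw$is_pits, raw$respondent_id, sum)
  if (any(pits_per_resp != 1L)) {
    bad <- names(pits_per_resp)[pits_per_resp != 1L]
    stop("each respondent needs exactly one pits task; offending: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  pits <- raw[raw$is_pits, c("respondent_id", "sg")]
  p_bounded <- bound_negative(pits$sg)
  names(p_bounded) <- as.character(pits$respondent_id)
  p_of <- p_bounded[as.character(raw$respondent_id)]
  y <- ifelse(raw$is_pits, p_of, adjust_sg(raw$sg, p_of))
  out <- data.frame(respondent_id = raw$respondent_id,
                    state_code = as.character(raw$state_code),
                    y = as.numeric(y),
                    is_pits = raw$is_pits,
                    stringsAsFactors = FALSE)
  if (!is.null(profiles)) {
    missing_ids <- setdiff(out$respondent_id, profiles$respondent_id)
    if (length(missing_ids) > 0) {
      stop("profiles missing for respondents: ",
           paste(utils::head(missing_ids, 5), collapse = ", "),
           call. = FALSE)
    }
    out <- merge(out, profiles, by = "respondent_id", sort = FALSE)
  }
  # stable ordering: respondent, then original task order
  out[order(match(out$respondent_id, unique(raw$respondent_id))), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Exclude respondents whose valuations never change
#'
#' A respondent who returns the same value for all eight tasks carries no
#' preference information and is dropped in full.
#'
#' @param data Adjusted valuations as produced by [build_dataset()].
#' @param tolerance Two values are "identical" when they differ by at most
#'   this much (default 0, exact equality).
#' @return A list with `data` (retained rows) and `excluded` (character
#'   vector of excluded respondent ids).
#' @export
filter_constant_respondents <- function(data, tolerance = 0) {
  rng <- tapply(data$y, data$respondent_id,
                function(v) diff(range(v)))
  excluded <- names(rng)[rng <= tolerance]
  keep <- !(as.character(data$respondent_id) %in% excluded)
  list(data = data[keep, , drop = FALSE], excluded = excluded)
}

#' Per-state summaries of adjusted valuations
#'
#' @param data Adjusted valuations with columns `state_code` and `y`.
#' @return Data frame with one row per distinct state: `state_code`, `n`,
#'   `mean`, `sd` (0 for a single record), `median`.
#' @export
state_summaries <- function(data) {
  stopifnot(nrow(data) > 0)
  sp <- split(data$y, data$state_code)
  out <- data.frame(
    state_code = names(sp),
    n = vapply(sp, length, integer(1)),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) else 0,
                numeric(1)),
    median = vapply(sp, stats::median, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Compress boundary values into the open unit interval
#'
#' The beta likelihood requires `0 < y < 1`. Utilities at exactly 0 or 1 can
#' optionally be compressed with the usual `(y * (n - 1) + 0.5) / n`
#' transformation before a beta-family fit.
#'
#' @param y Numeric vector of utilities in `[0, 1]`.
#' @return Compressed values, strictly inside (0, 1).
#' @export
compress_boundary <- function(y) {
  n <- length(y)
  (y * (n - 1) + 0.5) / n
}
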