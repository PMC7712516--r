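#' The SF-6D descriptive system
#'
#' The SF-6D classifies health on six dimensions: physical functioning (PF,
#' 6 levels), role limitations (RL, 4 levels), social functioning (SF, 5
#' levels), pain (PAIN, 6 levels), mental health (MH, 5 levels) and vitality
#' (VIT, 5 levels). Level 1 is no impairment; higher levels are more severe.
#' A health state is written as a six-digit code, one digit per dimension in
#' the order above, e.g. `"111111"` (full health) or `"645655"` (the "pits",
#' the worst definable state). The system defines
#' 6 * 4 * 5 * 6 * 5 * 5 = 18,000 states.
#'
#' @return A named integer vector giving the number of levels per dimension.
#' @examples
#' sf6d_dimensions()
#' prod(sf6d_dimensions())  # 18000
#' @export
sf6d_dimensions <- function() {
  c(PF = 6L, RL = 4L, SF = 5L, PAIN = 6L, MH = 5L, VIT = 5L)
}

#' Names of the 25 level dummy variables, in design-matrix column order
#'
#' One indicator per (dimension, level > 1) pair: PF2..PF6, RL2..RL4,
#' SF2..SF5, PAIN2..PAIN6, MH2..MH5, VIT2..VIT5.
#'
#' @return Character vector of length 25.
#' @export
sf6d_dummy_names <- function() {
  dims <- sf6d_dimensions()
  unlist(lapply(names(dims), function(d) paste0(d, 2:dims[[d]])),
         use.names = FALSE)
}

#' Parse an SF-6D state code
#'
#' Accepts the plain six-digit form (`"645655"`) or the comma-grouped form
#' used in print (`"645,655"`). Each digit must lie within its dimension's
#' level range.
#'
#' @param code Character scalar, a six-digit SF-6D state code.
#' @return Named integer vector of length 6 (PF, RL, SF, PAIN, MH, VIT).
#' @examples
#' parse_state_code("111111")
#' parse_state_code("645,655")
#' @export
parse_state_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code)) {
    stop("`code` must be a single character string", call. = FALSE)
  }
  plain <- gsub(",", "", code, fixed = TRUE)
  if (!grepl("^[0-9]{6}$", plain)) {
    stop("state code must consist of exactly 6 digits: ", sQuote(code),
         call. = FALSE)
  }
  lv <- as.integer(strsplit(plain, "")[[1]])
  dims <- sf6d_dimensions()
  names(lv) <- names(dims)
  bad <- lv < 1L | lv > dims
  if (any(bad)) {
    stop("level out of range in ", sQuote(plain), ": ",
         paste0(names(dims)[bad], "=", lv[bad], " (max ", dims[bad], ")",
                collapse = ", "),
         call. = FALSE)
  }
  lv
}

#' Format level vectors as six-digit state codes
#'
#' @param levels Integer vector of length 6, or a matrix with 6 columns
#'   (one row per state).
#' @return Character vector of state codes.
#' @export
state_code <- function(levels) {
  if (is.matrix(levels)) {
    apply(levels, 1L, paste0, collapse = "")
  } else {
    paste0(levels, collapse = "")
  }
}

#' Convert state codes to a matrix of levels
#'
#' @param codes Character vector of six-digit state codes.
#' @return Integer matrix with one row per code and columns PF, RL, SF,
#'   PAIN, MH, VIT.
#' @export
state_levels <- function(codes) {
  m <- t(vapply(codes, parse_state_code, integer(6)))
  dimnames(m) <- list(codes, names(sf6d_dimensions()))
  m
}

#' Enumerate all 18,000 SF-6D states
#'
#' Deterministic lexicographic order by level vector, so the first state is
#' full health `"111111"` and the last is the pits `"645655"`.
#'
#' @return Character vector of 18,000 state codes.
#' @export
enumerate_states <- function() {
  dims <- sf6d_dimensions()
  grids <- lapply(rev(unname(dims)), function(k) seq_len(k))
  g <- do.call(expand.grid, grids)  # varies first column fastest
  m <- as.matrix(g[, rev(seq_len(6L))])
  ord <- do.call(order, as.data.frame(m))
  state_code(m[ord, , drop = FALSE])
}

#' Dummy-variable design vector for one state
#'
#' Level 1 of every dimension is the reference; each level above 1 gets a
#' 0/1 indicator, 25 in total in the order of [sf6d_dummy_names()].
#'
#' @param state A state code or a length-6 level vector.
#' @return Named integer vector of length 25.
#' @examples
#' design_vector("645655")  # six indicators set
#' @export
design_vector <- function(state) {
  drop(design_matrix(if (is.character(state)) state else state_code(state)))
}

#' Dummy-variable design matrix for a set of states
#'
#' @param codes Character vector of state codes.
#' @return Integer matrix, `length(codes)` rows by 25 columns named as in
#'   [sf6d_dummy_names()].
#' @export
design_matrix <- function(codes) {
  lv <- state_levels(codes)
  dims <- sf6d_dimensions()
  nm <- sf6d_dummy_names()
  X <- matrix(0L, nrow = length(codes), ncol = length(nm),
              dimnames = list(codes, nm))
  for (d in names(dims)) {
    for (l in 2:dims[[d]]) {
      X[, paste0(d, l)] <- as.integer(lv[, d] == l)
    }
  }
  X
}

#' Adjacent states: one dimension, one level away
#'
#' Two states are adjacent when they differ in exactly one dimension and by
#' exactly one level. Every state has between 6 (corner states such as full
#' health or the pits) and 12 (all dimensions interior) neighbors.
#'
#' @param state A state code or length-6 level vector.
#' @return Character vector of neighboring state codes.
#' @examples
#' length(neighbors("111111"))  # 6
#' length(neighbors("323333"))  # 12
#' @export
neighbors <- function(state) {
  lv <- if (is.character(state)) parse_state_code(state) else {
    stopifnot(length(state) == 6L)
    as.integer(state)
  }
  dims <- sf6d_dimensions()
  out <- character(0)
  for (d in seq_len(6L)) {
    for (step in c(-1L, 1L)) {
      l2 <- lv[d] + step
      if (l2 >= 1L && l2 <= dims[[d]]) {
        nb <- lv
        nb[d] <- l2
        out <- c(out, state_code(nb))
      }
    }
  }
  out
}

#' Sample adjacent state pairs for the monotonicity audit
#'
#' First members are sampled without replacement from the full 18,000-state
#' space; the second member of each pair is drawn uniformly from the first's
#' 6-12 neighbors. The same unordered pair can arise twice via different
#' first members.
#'
#' @param n_states Number of pairs (at most 18,000).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A data frame with columns `state_a` and `state_b`; `state_b` is
#'   adjacent to `state_a`.
#' @export
sample_adjacent_pairs <- function(n_states, seed = 1L) {
  all_states <- enumerate_states()
  if (n_states > length(all_states)) {
    stop("n_states must be at most ", length(all_states), call. = FALSE)
  }
  with_seed(seed, {
    a <- all_states[sample.int(length(all_states), n_states)]
    b <- vapply(a, function(s) {
      nb <- neighbors(s)
      nb[sample.int(length(nb), 1L)]
    }, character(1))
    data.frame(state_a = a, state_b = unname(b), stringsAsFactors = FALSE)
  })
}

# Run `code` under a fixed seed, restoring the caller's RNG state afterwards
# so package functions never disturb the global stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}
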