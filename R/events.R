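#' The eight trial events
#'
#' Each T-maze trial resolves into one of eight joint outcomes, determined by
#' whether the rat attends to the lit light (T) or ignores it (~T), which arm
#' it chooses (A = left, B = right), and whether it is rewarded (O1) or not
#' (O2). The fixed E1..E8 ordering is used everywhere in the package —
#' probability vectors, operator indexing, sampling, and reporting.
#'
#' @return A data frame with one row per event and columns `event`
#'   (`"E1"`..`"E8"`), `index`, `attention` (`"T"` or `"~T"`), `light`
#'   (`"L"`, `"~L"`, or `"off"`), `choice` (`"A"`/`"B"`), and `outcome`
#'   (`"O1"`/`"O2"`).
#' @examples
#' event_table()
#' @export
event_table <- function() {
  data.frame(
    event = paste0("E", 1:8),
    index = 1:8,
    attention = c(rep("T", 4), rep("~T", 4)),
    light = c("L", "L", "~L", "~L", rep("off", 4)),
    choice = c("A", "A", "B", "B", "A", "A", "B", "B"),
    outcome = rep(c("O1", "O2"), 4),
    stringsAsFactors = FALSE
  )
}

#' Event probabilities at a given attention level
#'
#' The probability tree of one trial: with probability `x` the rat attends to
#' the lit light, with probability `1 - x` it ignores it; each light is lit on
#' half the trials; reward follows with probability `u1` or `u2` depending on
#' which light was lit. The eight leaf probabilities, in E1..E8 order, are
#' \deqn{(\tfrac12 u_1 x,\; \tfrac12(1-u_1)x,\; \tfrac12 u_2 x,\;
#'       \tfrac12(1-u_2)x,\; \tfrac12(1-x)u_1,\; \tfrac12(1-x)(1-u_1),\;
#'       \tfrac12(1-x)u_2,\; \tfrac12(1-x)(1-u_2)),}
#' which always sum to 1.
#'
#' @param x attention probability, in \[0, 1\]. May be a vector; the result is
#'   then a matrix with one row per element of `x`.
#' @param params a valid [model_params()] object.
#' @return For scalar `x`, a named numeric vector of 8 probabilities
#'   (`E1`..`E8`); for vector `x`, a `length(x)` by 8 matrix.
#' @examples
#' p <- model_params(rep(0.2, 8), rep(0, 8), u1 = 0.7, u2 = 0.4)
#' event_probabilities(0.6, p)
#' @export
event_probabilities <- function(x, params) {
  validate_params(params)
  x <- as.numeric(x)
  if (length(x) < 1L || anyNA(x) || any(x < 0) || any(x > 1))
    stop("field `x`: attention probability must lie in [0, 1]", call. = FALSE)
  u1 <- params$u1
  u2 <- params$u2
  m <- cbind(
    0.5 * u1 * x,
    0.5 * (1 - u1) * x,
    0.5 * u2 * x,
    0.5 * (1 - u2) * x,
    0.5 * (1 - x) * u1,
    0.5 * (1 - x) * (1 - u1),
    0.5 * (1 - x) * u2,
    0.5 * (1 - x) * (1 - u2)
  )
  colnames(m) <- paste0("E", 1:8)
  if (length(x) == 1L) m[1L, ] else m
}

#' Apply a learning operator
#'
#' After event `k` the attention probability is updated by the linear
#' operator \eqn{P_k x = \vartheta_k x + (1 - \vartheta_k)\lambda_k}, a convex
#' combination of the current state and the operator's limit point
#' \eqn{\lambda_k} (its fixed point). The map sends \[0, 1\] into \[0, 1\].
#'
#' @param k event index 1..8 (may be a vector, recycled against `x`).
#' @param x attention probability (scalar or vector).
#' @param params a valid [model_params()] object.
#' @return The updated attention probability (same length as the longer of
#'   `k`, `x`).
#' @examples
#' p <- model_params(rep(0.8, 8), rep(0.25, 8))
#' apply_operator(1, 0.5, p)   # 0.8 * 0.5 + 0.2 * 0.25 = 0.45
#' @export
apply_operator <- function(k, x, params) {
  validate_params(params)
  k <- as.integer(k)
  if (anyNA(k) || any(k < 1L) || any(k > 8L))
    stop("field `k`: event index must be in 1..8", call. = FALSE)
  x <- as.numeric(x)
  if (anyNA(x) || any(x < 0) || any(x > 1))
    stop("field `x`: attention probability must lie in [0, 1]", call. = FALSE)
  th <- params$theta[k]
  th * x + (1 - th) * params$lam[k]
}
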