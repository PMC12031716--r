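# Derive a reproducible child seed from a root seed. Children are spaced by
# a fixed odd stride and folded back into the 32-bit positive range, so
# per-block streams are deterministic given the root seed while distinct
# blocks get distinct streams.
child_seed <- function(root, index) {
  as.integer((as.double(root) + 9973 * as.double(index)) %% 2147483629)
}

# One vectorized trial step for a vector of path states: a single uniform
# draw per path, inverse-CDF over the cumulative event probabilities in
# fixed E1..E8 order.
step_paths <- function(x, params) {
  p <- event_probabilities(x, params)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  cum <- p
  for (k in 2:8) cum[, k] <- cum[, k - 1L] + cum[, k]
  u <- stats::runif(length(x))
  k <- rep(1L, length(x))
  for (j in 1:7) k <- k + (u > cum[, j])
  list(event = k, x = apply_operator(k, x, params))
}

#' Simulate one trial
#'
#' Samples one of the eight trial events at the current attention level (a
#' single uniform draw, inverse-CDF over the cumulative event probabilities
#' in fixed E1..E8 order) and applies the corresponding learning operator.
#'
#' @param x current attention probability in \[0, 1\].
#' @param params a valid [model_params()] object.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return A list with `event` (index 1..8) and `x` (the updated attention
#'   probability).
#' @export
simulate_trial <- function(x, params, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- as.numeric(x)[1L]
  if (is.na(x) || x < 0 || x > 1)
    stop("field `x`: attention probability must lie in [0, 1]", call. = FALSE)
  s <- step_paths(x, params)
  list(event = s$event[1L], x = s$x[1L])
}

#' Simulate a chain of trials
#'
#' Iterates [simulate_trial()] `n_trials` times, threading the attention
#' probability through the sampled learning operators.
#'
#' @param x0 initial attention probability.
#' @param n_trials number of trials (>= 0).
#' @param params a valid [model_params()] object.
#' @param seed optional integer seed.
#' @return An object of class `"trajectory"`: a data frame with columns
#'   `trial` (1..n), `x_before`, `event`, `x_after`, carrying `x0` as an
#'   attribute. Zero trials give a zero-row frame.
#' @examples
#' p <- make_special_case(model_params(rep(0.5, 8)), "all_one")
#' tr <- simulate_chain(0.2, 10, p, seed = 1)
#' all(diff(c(0.2, tr$x_after)) >= 0)   # absorption toward 1
#' @export
simulate_chain <- function(x0, n_trials, params, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  validate_params(params)
  x0 <- as.numeric(x0)[1L]
  if (is.na(x0) || x0 < 0 || x0 > 1)
    stop("field `x0`: initial probability must lie in [0, 1]", call. = FALSE)
  n_trials <- as.integer(n_trials)[1L]
  if (is.na(n_trials) || n_trials < 0L)
    stop("field `n_trials`: must be >= 0", call. = FALSE)
  x <- x0
  ev <- integer(n_trials)
  xb <- xa <- numeric(n_trials)
  for (n in seq_len(n_trials)) {
    xb[n] <- x
    s <- step_paths(x, params)
    ev[n] <- s$event
    x <- s$x
    xa[n] <- x
  }
  out <- data.frame(trial = seq_len(n_trials), x_before = xb,
                    event = ev, x_after = xa)
  attr(out, "x0") <- x0
  class(out) <- c("trajectory", "data.frame")
  out
}

# Vectorized simulation of n_paths independent chains for `depth` trials.
# Draws are trial-major (one uniform vector per trial across all paths),
# deterministic given the seed. Returns either the final states or the full
# n_paths x (depth + 1) state matrix.
sim_paths <- function(x0, depth, n_paths, params, keep_states = FALSE) {
  x <- rep(as.numeric(x0), length.out = n_paths)
  states <- if (keep_states)
    matrix(NA_real_, nrow = n_paths, ncol = depth + 1L) else NULL
  if (keep_states) states[, 1L] <- x
  for (n in seq_len(depth)) {
    x <- step_paths(x, params)$x
    if (keep_states) states[, n + 1L] <- x
  }
  if (keep_states) states else x
}

#' Learning curve across independent chains
#'
#' Mean and standard error of the attention probability at each trial index,
#' across `n_chains` independent chains started at `x0`. With a common
#' learning rate and limit point across events the mean follows the closed
#' form \eqn{E[x_n] = \lambda + \vartheta^n (x_0 - \lambda)}.
#'
#' @param x0 initial attention probability.
#' @param n_trials number of trials.
#' @param n_chains number of independent chains (>= 2).
#' @param params a valid [model_params()] object.
#' @param seed optional integer seed.
#' @return A data frame with columns `trial` (0..n_trials), `mean`, `stderr`.
#' @export
learning_curve <- function(x0, n_trials, n_chains, params, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  validate_params(params)
  n_chains <- as.integer(n_chains)[1L]
  if (is.na(n_chains) || n_chains < 2L)
    stop("field `n_chains`: must be >= 2", call. = FALSE)
  states <- sim_paths(x0, as.integer(n_trials), n_chains, params,
                      keep_states = TRUE)
  data.frame(
    trial = 0:n_trials,
    mean = colMeans(states),
    stderr = apply(states, 2L, stats::sd) / sqrt(n_chains)
  )
}

#' Monte Carlo estimate of a Picard iterate
#'
#' Runs `n_paths` independent chains of `depth` trials from `x0` and averages
#' a terminal function of the final state. Because each trial applies a
#' randomly selected learning operator with the event-tree probabilities,
#' the expectation of `terminal(X_depth)` equals the depth-`depth` Picard
#' iterate of the fixed-point operator started from `terminal`, evaluated at
#' `x0` (up to interpolation when `terminal` is a grid function). The
#' estimator is therefore unbiased for the deterministic iterate.
#'
#' @param x0 initial attention probability.
#' @param depth number of trials per path (>= 0).
#' @param n_paths number of independent paths (>= 1).
#' @param terminal `"identity"`, `"zero"`, a constant numeric scalar, or a
#'   [grid_function()] evaluated at the terminal state by interpolation.
#' @param params a valid [model_params()] object.
#' @param seed optional integer seed.
#' @return An object of class `"mc_estimate"`: a list with `point` (sample
#'   mean), `stderr` (sample standard deviation / sqrt(n_paths); 0 when all
#'   contributions are identical, `NA` for a single path), `n_paths`,
#'   `depth`, and `seed`.
#' @export
mc_estimate_W <- function(x0, depth, n_paths, terminal = "identity",
                          params, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  validate_params(params)
  depth <- as.integer(depth)[1L]
  n_paths <- as.integer(n_paths)[1L]
  if (is.na(depth) || depth < 0L)
    stop("field `depth`: must be >= 0", call. = FALSE)
  if (is.na(n_paths) || n_paths < 1L)
    stop("field `n_paths`: must be >= 1", call. = FALSE)
  xT <- if (depth == 0L) rep(as.numeric(x0), n_paths)
        else sim_paths(x0, depth, n_paths, params)
  contrib <- eval_terminal(terminal, xT)
  point <- mean(contrib)
  stderr <- if (n_paths == 1L) NA_real_
            else stats::sd(contrib) / sqrt(n_paths)
  structure(list(point = point, stderr = stderr, n_paths = n_paths,
                 depth = depth, seed = seed),
            class = "mc_estimate")
}

eval_terminal <- function(terminal, x) {
  if (inherits(terminal, "grid_function"))
    return(eval_grid_function(terminal, x))
  if (is.numeric(terminal))
    return(rep(as.numeric(terminal)[1L], length(x)))
  switch(match.arg(terminal, c("identity", "zero")),
         identity = x,
         zero = rep(0, length(x)))
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf(
    "MC estimate: %.6g (stderr %.3g, %d paths, depth %d)\n",
    x$point, x$stderr, x$n_paths, x$depth))
  invisible(x)
}

#' Compare the deterministic Picard iterate with Monte Carlo estimates
#'
#' For each starting point in `x0_grid`, computes the depth-`depth` Picard
#' iterate of the fixed-point operator started from `terminal` (by `depth`
#' applications of [apply_Z()] on a fine uniform grid) and the matching
#' Monte Carlo estimate, and tabulates their absolute difference against the
#' Monte Carlo standard error.
#'
#' @param params a valid [model_params()] object; a warning is issued when
#'   K1* >= 1 since the iterates then need not settle.
#' @param x0_grid starting points in \[0, 1\].
#' @param depth iterate depth / trials per path.
#' @param n_paths Monte Carlo paths per starting point.
#' @param terminal terminal function, as in [mc_estimate_W()].
#' @param seed optional integer root seed; each starting point uses a child
#'   seed derived from it.
#' @param n_nodes grid resolution for the deterministic iterate.
#' @return A data frame of class `"solver_comparison"` with columns `x0`,
#'   `deterministic`, `mc`, `abs_error`, `stderr`, carrying attributes
#'   `max_abs_error` and `mean_stderr`.
#' @export
compare_solvers <- function(params, x0_grid = seq(0, 1, length.out = 21),
                            depth = 20L, n_paths = 10000L,
                            terminal = "identity", seed = NULL,
                            n_nodes = 2001L) {
  validate_params(params)
  K1 <- contraction_constants(params)$K1
  if (K1 >= 1)
    warning(sprintf("K1* = %.4g >= 1: iterates may not contract", K1),
            call. = FALSE)
  x0_grid <- as.numeric(x0_grid)
  root <- if (is.null(seed)) sample.int(2147483000L, 1L) else as.integer(seed)

  W <- if (inherits(terminal, "grid_function")) terminal
       else uniform_grid_function(n_nodes, init_from_terminal(terminal))
  for (i in seq_len(depth)) W <- apply_Z(W, params)
  det <- eval_grid_function(W, x0_grid)

  mc <- se <- numeric(length(x0_grid))
  for (i in seq_along(x0_grid)) {
    est <- mc_estimate_W(x0_grid[i], depth, n_paths, terminal, params,
                         seed = child_seed(root, i))
    mc[i] <- est$point
    se[i] <- est$stderr
  }
  out <- data.frame(x0 = x0_grid, deterministic = det, mc = mc,
                    abs_error = abs(det - mc), stderr = se)
  attr(out, "max_abs_error") <- max(out$abs_error)
  attr(out, "mean_stderr") <- mean(se)
  class(out) <- c("solver_comparison", "data.frame")
  out
}

init_from_terminal <- function(terminal) {
  if (is.numeric(terminal)) {
    cval <- as.numeric(terminal)[1L]
    function(x) rep(cval, length(x))
  } else {
    match.arg(terminal, c("identity", "zero"))
  }
}
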