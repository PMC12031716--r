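#' Apply the fixed-point operator Z to a grid function
#'
#' One application of the model's fixed-point operator:
#' \deqn{(ZW)(x) = \sum_{k=1}^{8} p_k(x)\, W(P_k x),}
#' where \eqn{p_k(x)} are the eight event probabilities at attention level x
#' and \eqn{P_k x = \vartheta_k x + (1-\vartheta_k)\lambda_k} are the learning
#' operators. The arguments \eqn{P_k x} rarely land on grid nodes, so W is
#' evaluated there by linear interpolation; the output is defined on the same
#' nodes as the input.
#'
#' Because the coefficients \eqn{p_k(x)} are nonnegative and sum to 1, ZW is
#' at every node a convex combination of values of W: Z preserves nodewise
#' bounds, is monotone in W, and maps constants to themselves.
#'
#' @param W a [grid_function()].
#' @param params a valid [model_params()] object.
#' @return A `grid_function` on the same nodes.
#' @examples
#' p <- model_params(rep(0.5, 8), rep(0, 8))
#' W <- uniform_grid_function(11, "identity")
#' apply_Z(W, p)$values   # equals 0.5 * nodes here
#' @export
apply_Z <- function(W, params) {
  stopifnot(inherits(W, "grid_function"))
  validate_params(params)
  x <- W$nodes
  p <- event_probabilities(x, params)       # length(x) x 8
  out <- numeric(length(x))
  for (k in 1:8) {
    xk <- params$theta[k] * x + (1 - params$theta[k]) * params$lam[k]
    out <- out + p[, k] * stats::approx(W$nodes, W$values, xout = xk)$y
  }
  grid_function(x, out)
}

#' Solver options for the Picard iteration
#'
#' @param mode `"free"` runs the plain iteration `W_n = Z W_{n-1}`; `"pinned"`
#'   additionally clamps the endpoint values `W(0)`, `W(1)` to
#'   `boundary_values` after every application of Z, producing a nontrivial
#'   absorption-style solution (the free iteration converges to a constant
#'   function for contraction parameters).
#' @param boundary_values length-2 numeric `(W(0), W(1))` used in pinned mode.
#' @param tol sup-norm convergence tolerance on successive iterates.
#' @param max_iter iteration cap.
#' @param init `"zero"`, `"identity"`, or a custom [grid_function()] used as
#'   the starting iterate.
#' @param n_nodes number of uniform grid nodes when `init` is a name.
#' @return An object of class `"solver_options"`.
#' @export
solver_options <- function(mode = c("free", "pinned"),
                           boundary_values = c(0, 1),
                           tol = 1e-10, max_iter = 10000L,
                           init = "zero", n_nodes = 1001L) {
  mode <- match.arg(mode)
  tol <- as.numeric(tol)[1L]
  max_iter <- as.integer(max_iter)[1L]
  if (is.na(tol) || tol <= 0)
    stop("field `tol`: must be > 0", call. = FALSE)
  if (is.na(max_iter) || max_iter < 1L)
    stop("field `max_iter`: must be >= 1", call. = FALSE)
  if (mode == "pinned") {
    boundary_values <- as.numeric(boundary_values)
    if (length(boundary_values) != 2L || anyNA(boundary_values))
      stop("pinned mode requires two finite boundary values", call. = FALSE)
  }
  if (!(is.character(init) && init %in% c("zero", "identity")) &&
      !inherits(init, "grid_function"))
    stop("field `init`: must be \"zero\", \"identity\", or a grid_function",
         call. = FALSE)
  structure(list(mode = mode, boundary_values = boundary_values, tol = tol,
                 max_iter = max_iter, init = init,
                 n_nodes = as.integer(n_nodes)),
            class = "solver_options")
}

#' Picard iteration for the functional equation
#'
#' Iterates `W_n = Z W_{n-1}` from the chosen initial function until the
#' maximum change between successive approximations over the grid nodes drops
#' to `tol`, or `max_iter` is reached. When the contraction constant K1* is
#' below 1 the iteration converges to the unique solution of the discretized
#' equation (in free mode, a constant function; the zero function when
#' started from zero). Pinned mode clamps `W(0)` and `W(1)` after each sweep,
#' yielding a nontrivial solution of the clamped iteration.
#'
#' @param params a valid [model_params()] object.
#' @param options a [solver_options()] object.
#' @return A list with components `W` (the final `grid_function`) and
#'   `report` (a `convergence_report`: `iterations`, `sup_deltas` — the full
#'   per-iteration history of max absolute nodewise change, `empirical_rate`
#'   — the geometric-mean ratio of successive sup-deltas, `K1`, `converged`).
#'   In free mode non-convergence at `max_iter` raises a warning naming K1*.
#' @examples
#' p <- model_params(rep(0.2, 8), rep(0, 8))
#' fit <- picard_solve(p, solver_options(init = "identity", n_nodes = 101))
#' fit$report$converged
#' @export
picard_solve <- function(params, options = solver_options()) {
  validate_params(params)
  stopifnot(inherits(options, "solver_options"))
  W <- if (inherits(options$init, "grid_function")) {
    options$init
  } else {
    uniform_grid_function(options$n_nodes, options$init)
  }
  pin <- options$mode == "pinned"
  if (pin) {
    W$values[1L] <- options$boundary_values[1L]
    W$values[length(W$values)] <- options$boundary_values[2L]
  }
  K1 <- contraction_constants(params)$K1
  sup_deltas <- numeric(0)
  converged <- FALSE
  for (it in seq_len(options$max_iter)) {
    Wnew <- apply_Z(W, params)
    if (pin) {
      Wnew$values[1L] <- options$boundary_values[1L]
      Wnew$values[length(Wnew$values)] <- options$boundary_values[2L]
    }
    d <- max(abs(Wnew$values - W$values))
    sup_deltas <- c(sup_deltas, d)
    W <- Wnew
    if (d <= options$tol) {
      converged <- TRUE
      break
    }
  }
  # geometric-mean contraction rate over the recorded positive deltas
  pos <- sup_deltas[sup_deltas > 0]
  empirical_rate <- if (length(pos) >= 2L) {
    exp(mean(diff(log(pos))))
  } else {
    NA_real_
  }
  if (!converged)
    warning(sprintf(
      "Picard iteration did not reach tol = %g within %d iterations (K1* = %.4g)",
      options$tol, options$max_iter, K1), call. = FALSE)
  report <- structure(list(
    iterations = length(sup_deltas),
    sup_deltas = sup_deltas,
    empirical_rate = empirical_rate,
    K1 = K1,
    converged = converged
  ), class = "convergence_report")
  list(W = W, report = report)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf(
    "Picard iteration: %d iteration(s), converged: %s\n",
    x$iterations, if (x$converged) "yes" else "no"))
  cat(sprintf("  final sup-delta = %.4g, empirical rate = %.4g, K1* = %.4g\n",
              if (x$iterations) x$sup_deltas[x$iterations] else NA_real_,
              x$empirical_rate, x$K1))
  invisible(x)
}

#' Write a convergence report to CSV
#'
#' Columns `iter` and `sup_delta`, one row per iteration.
#'
#' @param report a `convergence_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_convergence_report <- function(report, path) {
  stopifnot(inherits(report, "convergence_report"))
  utils::write.csv(
    data.frame(iter = seq_along(report$sup_deltas),
               sup_delta = report$sup_deltas),
    path, row.names = FALSE)
  invisible(path)
}
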