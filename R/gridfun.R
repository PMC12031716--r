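#' Discretized functions on \[0, 1\]
#'
#' The asymptotic choice-probability function W and its Picard iterates are
#' represented by their values on a grid of nodes spanning \[0, 1\], with
#' linear interpolation between nodes. Nodes must be strictly increasing and
#' include both endpoints.
#'
#' @param nodes strictly increasing numeric vector with `nodes[1] == 0` and
#'   `nodes[length(nodes)] == 1`; at least 3 nodes.
#' @param values numeric vector of the same length: W at each node.
#' @return An object of class `"grid_function"`.
#' @examples
#' grid_function(seq(0, 1, by = 0.25), c(0, 0.2, 0.5, 0.9, 1))
#' @export
grid_function <- function(nodes, values) {
  nodes <- as.numeric(nodes)
  values <- as.numeric(values)
  if (length(nodes) < 3L)
    stop("grid_function needs at least 3 nodes", call. = FALSE)
  if (length(values) != length(nodes))
    stop("`nodes` and `values` must have equal length", call. = FALSE)
  if (anyNA(nodes) || anyNA(values))
    stop("nodes and values must be finite", call. = FALSE)
  if (nodes[1L] != 0 || nodes[length(nodes)] != 1)
    stop("nodes must span [0, 1] including both endpoints", call. = FALSE)
  if (any(diff(nodes) <= 0))
    stop("nodes must be strictly increasing", call. = FALSE)
  structure(list(nodes = nodes, values = values), class = "grid_function")
}

#' Construct a uniform grid function from a named initialization
#'
#' @param n_nodes number of nodes (default 1001).
#' @param init `"zero"`, `"identity"`, or a function of x evaluated at the
#'   nodes.
#' @return A `grid_function` on the uniform grid.
#' @export
uniform_grid_function <- function(n_nodes = 1001L, init = "zero") {
  nodes <- seq(0, 1, length.out = as.integer(n_nodes))
  values <- if (is.function(init)) {
    init(nodes)
  } else {
    switch(match.arg(init, c("zero", "identity")),
           zero = rep(0, length(nodes)),
           identity = nodes)
  }
  grid_function(nodes, values)
}

#' Evaluate a grid function by linear interpolation
#'
#' @param W a `grid_function`.
#' @param x points in \[0, 1\] at which to evaluate.
#' @return Numeric vector of interpolated values.
#' @export
eval_grid_function <- function(W, x) {
  stopifnot(inherits(W, "grid_function"))
  stats::approx(W$nodes, W$values, xout = x, rule = 2)$y
}

#' @export
print.grid_function <- function(x, ...) {
  cat(sprintf("grid_function on %d nodes over [0, 1]; W(0) = %.6g, W(1) = %.6g\n",
              length(x$nodes), x$values[1L], x$values[length(x$values)]))
  invisible(x)
}

#' Discrete Lipschitz seminorm
#'
#' The seminorm \eqn{\sup_{a \ne b} |W(a) - W(b)| / |a - b|} of the
#' underlying function space, evaluated for the piecewise-linear interpolant:
#' the maximum over all node pairs is attained on an adjacent pair, so only
#' adjacent-segment slopes are scanned (O(n)).
#'
#' @param W a `grid_function` (at least 2 nodes).
#' @return Nonnegative scalar: the maximum absolute adjacent-segment slope.
#' @examples
#' lipschitz_seminorm(grid_function(c(0, 0.5, 1), c(0, 0.5, 1)))  # 1
#' @export
lipschitz_seminorm <- function(W) {
  if (!inherits(W, "grid_function"))
    stop("`W` must be a grid_function", call. = FALSE)
  if (length(W$nodes) < 2L)
    stop("lipschitz_seminorm needs at least 2 nodes", call. = FALSE)
  max(abs(diff(W$values) / diff(W$nodes)))
}

#' Boundary behavior probe
#'
#' One-sided finite-difference slopes of W near the endpoints of \[0, 1\],
#' used to report asymptotic behavior of the solved function as x approaches
#' 0 and 1.
#'
#' @param W a `grid_function`.
#' @param epsilon offset for the one-sided differences; must satisfy
#'   `0 < epsilon < 0.5`.
#' @return A list with `slope0 = (W(eps) - W(0)) / eps`,
#'   `slope1 = (W(1) - W(1 - eps)) / eps`, `value0 = W(0)`, `value1 = W(1)`.
#' @export
boundary_probe <- function(W, epsilon = 1e-3) {
  stopifnot(inherits(W, "grid_function"))
  epsilon <- as.numeric(epsilon)[1L]
  if (is.na(epsilon) || epsilon <= 0 || epsilon >= 0.5)
    stop("field `epsilon`: must satisfy 0 < epsilon < 0.5", call. = FALSE)
  v0 <- W$values[1L]
  v1 <- W$values[length(W$values)]
  list(
    slope0 = (eval_grid_function(W, epsilon) - v0) / epsilon,
    slope1 = (v1 - eval_grid_function(W, 1 - epsilon)) / epsilon,
    value0 = v0,
    value1 = v1
  )
}

#' Write a grid function to CSV
#'
#' Columns `x` and `W`, one row per node.
#'
#' @param W a `grid_function`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid_function <- function(W, path) {
  stopifnot(inherits(W, "grid_function"))
  utils::write.csv(data.frame(x = W$nodes, W = W$values), path,
                   row.names = FALSE)
  invisible(path)
}
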