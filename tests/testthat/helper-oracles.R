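# Independent oracles, written without reference to the package internals.

# Brute-force application of the fixed-point operator: explicit 8-term
# summation with its own hand-rolled linear interpolation.
oracle_Z <- function(nodes, values, theta, lam, u1, u2) {
  interp <- function(x) {
    if (x <= nodes[1L]) return(values[1L])
    if (x >= nodes[length(nodes)]) return(values[length(values)])
    j <- max(which(nodes <= x))
    if (nodes[j] == x) return(values[j])
    t <- (x - nodes[j]) / (nodes[j + 1L] - nodes[j])
    (1 - t) * values[j] + t * values[j + 1L]
  }
  probs <- function(x) c(0.5 * u1 * x, 0.5 * (1 - u1) * x,
                         0.5 * u2 * x, 0.5 * (1 - u2) * x,
                         0.5 * (1 - x) * u1, 0.5 * (1 - x) * (1 - u1),
                         0.5 * (1 - x) * u2, 0.5 * (1 - x) * (1 - u2))
  vapply(nodes, function(x) {
    acc <- 0
    pk <- probs(x)
    for (k in 1:8)
      acc <- acc + pk[k] * interp(theta[k] * x + (1 - theta[k]) * lam[k])
    acc
  }, numeric(1))
}

# All-pairs Lipschitz quotient (O(n^2)), against which the adjacent-segment
# implementation is checked.
oracle_lipschitz <- function(nodes, values) {
  best <- 0
  n <- length(nodes)
  for (a in 1:(n - 1)) for (b in (a + 1):n)
    best <- max(best, abs(values[b] - values[a]) / (nodes[b] - nodes[a]))
  best
}

# Random fixture draws used across test files.
rand_contraction_params <- function(seed) {
  sample_params(seed = seed, require_contraction = TRUE,
                theta_range = c(0.01, 0.3), lam_range = c(0, 0.3))
}

# Vectorized single-trial event draw (internal engine), for frequency checks.
step_paths_for_test <- function(x, params) {
  tmazelearn:::step_paths(x, params)$event
}

rand_grid_function <- function(n_nodes = 5L) {
  grid_function(seq(0, 1, length.out = n_nodes),
                stats::runif(n_nodes, -1, 1))
}
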