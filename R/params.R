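#' Model parameters for the T-maze learning model
#'
#' Bundles the full parameter vector of the stochastic discrimination-learning
#' model: eight learning rates \eqn{\vartheta_1,\dots,\vartheta_8} (one per
#' trial event), eight operator limit points \eqn{\lambda_1,\dots,\lambda_8},
#' and the two reward probabilities \eqn{u_1} (light-on trials) and \eqn{u_2}
#' (light-off-side trials).
#'
#' Learning rates are constrained to the open interval (0, 1): a rate of 0
#' would make an operator jump straight to its limit point, a rate of 1 would
#' freeze the state; neither corresponds to the gradual linear learning the
#' model describes. Limit points and reward probabilities live in the closed
#' interval \[0, 1\].
#'
#' @param theta numeric vector of 8 learning rates, each strictly in (0, 1).
#' @param lam numeric vector of 8 operator limit points in \[0, 1\].
#' @param u1 reward probability on trials where the left light is lit.
#' @param u2 reward probability on trials where the right light is lit.
#'
#' @return An object of class `"model_params"`: a list with elements
#'   `theta`, `lam`, `u1`, `u2`.
#'
#' @examples
#' p <- model_params(theta = rep(0.2, 8), lam = rep(0, 8), u1 = 0.5, u2 = 0.5)
#' p
#' @export
model_params <- function(theta, lam = rep(0, 8), u1 = 0.5, u2 = 0.5) {
  theta <- as.numeric(theta)
  lam <- as.numeric(lam)
  u1 <- as.numeric(u1)[1L]
  u2 <- as.numeric(u2)[1L]
  obj <- structure(list(theta = theta, lam = lam, u1 = u1, u2 = u2),
                   class = "model_params")
  validate_params(obj)
  obj
}

#' Validate a model_params object
#'
#' Checks the structural invariants of the parameter vector and stops with a
#' message naming the offending field on failure.
#'
#' @param params an object to validate.
#' @return `params`, invisibly, when valid.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "model_params"))
    stop("`params` must be a model_params object", call. = FALSE)
  th <- params$theta
  lm <- params$lam
  if (length(th) != 8L || anyNA(th))
    stop("field `theta`: must be 8 finite learning rates", call. = FALSE)
  if (any(th <= 0) || any(th >= 1))
    stop("field `theta`: learning rates must lie strictly in (0, 1); got [",
         paste(signif(th, 4), collapse = ", "), "]", call. = FALSE)
  if (length(lm) != 8L || anyNA(lm) || any(lm < 0) || any(lm > 1))
    stop("field `lam`: limit points must be 8 values in [0, 1]", call. = FALSE)
  for (nm in c("u1", "u2")) {
    u <- params[[nm]]
    if (length(u) != 1L || is.na(u) || u < 0 || u > 1)
      stop("field `", nm, "`: must be a single probability in [0, 1]",
           call. = FALSE)
  }
  invisible(params)
}

#' @export
print.model_params <- function(x, ...) {
  cat("T-maze learning model parameters\n")
  cat("  theta (learning rates): ",
      paste(signif(x$theta, 4), collapse = " "), "\n")
  cat("  lambda (limit points) : ",
      paste(signif(x$lam, 4), collapse = " "), "\n")
  cat(sprintf("  u1 = %.4g, u2 = %.4g\n", x$u1, x$u2))
  invisible(x)
}

#' Special-case parameter regimes
#'
#' Overwrites the limit-point vector of a parameter set to place the model in
#' one of its analytically distinguished regimes:
#' \describe{
#'   \item{`general`}{identity: the base parameters are returned unchanged.}
#'   \item{`common_lambda`}{all eight operators share a single limit point
#'     (the commutative condition); requires `lam_value`.}
#'   \item{`all_zero`}{every limit point is 0 — extinction of a behavioral
#'     reflex; all operators shrink the state toward 0.}
#'   \item{`all_one`}{every limit point is 1 — consistent food-side choice;
#'     all operators push the state toward 1.}
#' }
#'
#' @param base a valid [model_params()] object.
#' @param case one of `"general"`, `"common_lambda"`, `"all_zero"`,
#'   `"all_one"`.
#' @param lam_value the shared limit point when `case = "common_lambda"`.
#' @return A `model_params` object with the limit points overwritten.
#' @examples
#' p <- model_params(rep(0.3, 8), runif(8), 0.6, 0.4)
#' make_special_case(p, "all_zero")$lam
#' @export
make_special_case <- function(base,
                              case = c("general", "common_lambda",
                                       "all_zero", "all_one"),
                              lam_value = NULL) {
  validate_params(base)
  case <- match.arg(case)
  lam <- switch(case,
    general = base$lam,
    all_zero = rep(0, 8),
    all_one = rep(1, 8),
    common_lambda = {
      if (is.null(lam_value))
        stop("case `common_lambda` requires `lam_value`", call. = FALSE)
      lam_value <- as.numeric(lam_value)[1L]
      if (is.na(lam_value) || lam_value < 0 || lam_value > 1)
        stop("field `lam_value`: must be a probability in [0, 1]",
             call. = FALSE)
      rep(lam_value, 8)
    })
  model_params(base$theta, lam, base$u1, base$u2)
}

#' Sample a random parameter set
#'
#' Draws a valid parameter set uniformly over its box: learning rates uniform
#' on (0, 1), limit points and reward probabilities uniform on \[0, 1\]. With
#' `require_contraction = TRUE`, rejection-samples until the contraction
#' constant K1* (as printed) is below 1, which guarantees the model's
#' functional equation is solvable by Picard iteration. K1* < 1 forces small
#' learning rates and limit points, so the accepted region is a small corner
#' of the box; the rejection loop is capped.
#'
#' @param seed optional integer seed making the draw reproducible; `NULL`
#'   uses the current RNG state.
#' @param require_contraction logical; if `TRUE`, only return parameter sets
#'   with K1* < 1.
#' @param theta_range,lam_range,u_range length-2 sampling intervals for the
#'   learning rates, limit points, and reward probabilities. K1* averages
#'   the per-event sums of two learning rates plus limit-point terms over
#'   the trial tree (total weight 2), so K1* < 1 is a rare event under the
#'   full box; shrinking `theta_range`/`lam_range` makes rejection sampling
#'   practical.
#' @param max_draws cap on rejection draws before giving up.
#' @return A `model_params` object.
#' @examples
#' sample_params(seed = 1)
#' sample_params(seed = 1, require_contraction = TRUE,
#'               theta_range = c(0.01, 0.3), lam_range = c(0, 0.3))
#' @export
sample_params <- function(seed = NULL, require_contraction = FALSE,
                          theta_range = c(0, 1), lam_range = c(0, 1),
                          u_range = c(0, 1), max_draws = 10000L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  for (i in seq_len(max_draws)) {
    th <- stats::runif(8, theta_range[1L], theta_range[2L])
    # guard the open interval against a boundary draw
    th <- pmin(pmax(th, .Machine$double.eps), 1 - .Machine$double.eps)
    p <- model_params(th, stats::runif(8, lam_range[1L], lam_range[2L]),
                      stats::runif(1, u_range[1L], u_range[2L]),
                      stats::runif(1, u_range[1L], u_range[2L]))
    if (!require_contraction) return(p)
    if (contraction_constants(p)$K1 < 1) return(p)
  }
  stop("no contraction parameter set found in ", max_draws,
       " draws; K1* < 1 requires small learning rates and limit points - ",
       "consider sampling theta and lambda over a narrower range",
       call. = FALSE)
}

#' Serialize parameters to a flat configuration list
#'
#' Flattens a parameter set into named scalar entries
#' `theta1..theta8`, `lambda1..lambda8`, `u1`, `u2`, the layout used by the
#' YAML/JSON configuration files of the command-line interface.
#'
#' @param params a valid `model_params` object.
#' @return A named list of 18 scalars.
#' @seealso [params_from_config()]
#' @export
params_to_config <- function(params) {
  validate_params(params)
  out <- c(as.list(stats::setNames(params$theta, paste0("theta", 1:8))),
           as.list(stats::setNames(params$lam, paste0("lambda", 1:8))),
           list(u1 = params$u1, u2 = params$u2))
  out
}

#' Build parameters from a flat configuration list
#'
#' Inverse of [params_to_config()]. Unknown keys are rejected so that typos
#' (e.g. `theta9`) fail loudly rather than being silently ignored.
#'
#' @param config a named list with keys `theta1..theta8`, `lambda1..lambda8`,
#'   `u1`, `u2`.
#' @return A `model_params` object.
#' @export
params_from_config <- function(config) {
  if (!is.list(config) || is.null(names(config)))
    stop("params config must be a named list", call. = FALSE)
  wanted <- c(paste0("theta", 1:8), paste0("lambda", 1:8), "u1", "u2")
  unknown <- setdiff(names(config), wanted)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(wanted, names(config))
  if (length(missing))
    stop("missing parameter key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  num <- vapply(config[wanted], function(v) as.numeric(v)[1L], numeric(1))
  model_params(num[1:8], num[9:16], num[["u1"]], num[["u2"]])
}

#' Read/write parameter sets as JSON or YAML
#'
#' The file format is chosen from the extension: `.json` uses JSON, `.yaml`
#' or `.yml` uses YAML.
#'
#' @param params a `model_params` object.
#' @param path file path ending in `.json`, `.yaml`, or `.yml`.
#' @return `read_params()` returns a `model_params`; `write_params()` returns
#'   `path` invisibly.
#' @export
write_params <- function(params, path) {
  cfg <- params_to_config(params)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(cfg, path)
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  params_from_config(as.list(cfg))
}
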