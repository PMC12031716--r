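#' Contraction constants K1*-K4*
#'
#' Closed-form constants bounding the Lipschitz factor of the model's
#' fixed-point operator in the Lipschitz seminorm. `K1` applies to the
#' general model: when K1* < 1 the operator is a Banach contraction and
#' Picard iteration converges to the unique solution of the functional
#' equation. `K2` is the analogue stated for the common-limit-point
#' (commutative) regime and uses a single shared lambda; it is therefore
#' reported only when all limit points are equal, and is `NA` (flagged
#' `K2_applicable = FALSE`) otherwise. `K3` covers the reflex-extinction
#' regime (all limit points 0) and equals K1* evaluated at lambda = 0. `K4`
#' covers the food-side-absorption regime (all limit points 1); note that as
#' stated K4* = 2 + K3* > 2, so its contraction hypothesis K4* < 1 can never
#' hold for valid parameters — the diagnostic exposes this rather than
#' guessing an alternative formula.
#'
#' The printed K2* formula contains a `(theta3 + theta3)` term where the
#' pattern of the other three rows implies `(theta3 + theta7)`.
#' `variant = "as_printed"` (the default) evaluates the formula verbatim;
#' `variant = "typo_corrected"` uses `theta3 + theta7`. Both flags are
#' recorded in the result.
#'
#' Each constant is a sum of nonnegative row terms wrapped in an absolute
#' value; the rows are summed and the absolute value applied to the total
#' (inert for valid parameters since all summands are nonnegative).
#'
#' @param params a valid [model_params()] object.
#' @param variant `"as_printed"` or `"typo_corrected"` (affects K2 only).
#' @return An object of class `"contraction_diagnostics"`: a list with
#'   numeric `K1`, `K2`, `K3`, `K4`, the logical flags `K2_applicable`,
#'   `K2_as_printed`, `typo_corrected`, the `variant` string, and
#'   `contraction` (`TRUE` iff K1* < 1).
#' @examples
#' p <- model_params(rep(0.2, 8), rep(0, 8))
#' contraction_constants(p)   # K1 = K3 = 0.8, contraction holds
#' @export
contraction_constants <- function(params,
                                  variant = c("as_printed",
                                              "typo_corrected")) {
  validate_params(params)
  variant <- match.arg(variant)
  th <- params$theta
  lm <- params$lam
  u1 <- params$u1
  u2 <- params$u2
  w <- c(u1, 1 - u1, u2, 1 - u2)           # group weights, pairs (1,5)..(4,8)
  i <- 1:4
  j <- 5:8

  K1 <- abs(sum(w * (th[i] + th[j] +
                       0.5 * (1 - th[i]) * lm[i] +
                       0.5 * (1 - th[j]) * lm[j])))
  K3 <- abs(sum(w * (th[i] + th[j])))
  K4 <- abs(sum(w * (1 + th[i] + th[j])))

  common <- length(unique(lm)) == 1L
  if (common) {
    lam <- lm[1L]
    th3p <- if (variant == "as_printed") th[3] + th[3] else th[3] + th[7]
    pairs <- c(th[1] + th[5], th[2] + th[6], th3p, th[4] + th[8])
    K2 <- abs(sum(w * (lam + (1 - lam / 2) * pairs)))
  } else {
    K2 <- NA_real_
  }

  structure(list(
    K1 = K1, K2 = K2, K3 = K3, K4 = K4,
    K2_applicable = common,
    K2_as_printed = variant == "as_printed",
    typo_corrected = variant == "typo_corrected",
    variant = variant,
    contraction = K1 < 1
  ), class = "contraction_diagnostics")
}

#' @export
print.contraction_diagnostics <- function(x, ...) {
  cat("Contraction diagnostics (variant:", x$variant, ")\n")
  cat(sprintf("  K1* = %.6g   (contraction: %s)\n", x$K1,
              if (x$contraction) "yes" else "no"))
  if (x$K2_applicable) {
    cat(sprintf("  K2* = %.6g   (common-lambda regime)\n", x$K2))
  } else {
    cat("  K2* = not applicable (limit points are not all equal)\n")
  }
  cat(sprintf("  K3* = %.6g   (reflex-extinction regime)\n", x$K3))
  cat(sprintf("  K4* = %.6g   (always > 2 as stated)\n", x$K4))
  invisible(x)
}

#' Export contraction diagnostics as a one-row data frame
#'
#' Convenience layout for CSV export, with columns `K1`, `K2`, `K3`, `K4`,
#' `variant`.
#'
#' @param diag a `contraction_diagnostics` object.
#' @return A one-row data frame.
#' @export
diagnostics_to_df <- function(diag) {
  stopifnot(inherits(diag, "contraction_diagnostics"))
  data.frame(K1 = diag$K1, K2 = diag$K2, K3 = diag$K3, K4 = diag$K4,
             variant = diag$variant, stringsAsFactors = FALSE)
}
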