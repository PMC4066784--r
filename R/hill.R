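#' Hill fold-change regulation function
#'
#' Multiplier applied to a basal synthesis rate by one regulatory link,
#' \deqn{F(x) = \frac{1 + f (x/K)^n}{1 + (x/K)^n}.}
#' The function interpolates between 1 (no regulator, `x = 0`) and the fold
#' change `f` (saturating regulator), so `f > 1` encodes activation,
#' `0 < f < 1` repression and `f = 1` a null (absent) link.
#'
#' @param x Regulator level, normalized concentration units (>= 0). Vectorized.
#' @param f Fold change (> 0).
#' @param K Half-saturation level, normalized concentration units (> 0).
#' @param n Effective cooperativity (Hill exponent, >= 1).
#' @return Numeric vector of fold-change multipliers, strictly between
#'   `min(1, f)` and `max(1, f)` for `x > 0`.
#' @examples
#' hill_fold(0, f = 3, K = 0.5, n = 2)   # 1: no regulator present
#' hill_fold(0.5, f = 3, K = 0.5, n = 2) # (1 + f)/2: half-saturation
#' @export
hill_fold <- function(x, f, K, n) {
  check_hill_params(f, K, n)
  if (any(!is.finite(x) | x < 0)) {
    abort("`x` must be finite and non-negative.", class = "ergnet_invalid_parameter")
  }
  u <- (x / K)^n
  (1 + f * u) / (1 + u)
}

# derivative dF/dx, used for Jacobians
hill_fold_deriv <- function(x, f, K, n) {
  if (f == 1) return(rep(0, length(x)))
  u <- (x / K)^n
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- (f - 1) * n * u[pos] / (x[pos] * (1 + u[pos])^2)
  # at x = 0 the derivative is 0 for n > 1 and (f-1)*n/K for n == 1
  if (any(!pos) && n == 1) out[!pos] <- (f - 1) / K
  out
}

check_hill_params <- function(f, K, n) {
  ok <- is.finite(f) && is.finite(K) && is.finite(n) && f > 0 && K > 0 && n >= 1
  if (!ok) {
    abort("Hill parameters require f > 0, K > 0, n >= 1 and all finite.",
          class = "ergnet_invalid_parameter")
  }
  invisible(TRUE)
}

#' Logarithmic gain of a Hill regulation function
#'
#' Local elasticity \eqn{d\log F / d\log x} of [hill_fold()] at level `x`,
#' the measure of regulatory-link strength at an operating point. Closed
#' form: \eqn{n u (f - 1) / [(1 + u)(1 + f u)]} with \eqn{u = (x/K)^n}.
#' Its sign equals `sign(f - 1)`; a null link (`f = 1`) has zero gain
#' everywhere.
#'
#' @inheritParams hill_fold
#' @param x Evaluation level (> 0). Vectorized.
#' @return Dimensionless gain.
#' @examples
#' log_gain(x = 0.5, f = 3, K = 0.5, n = 2) # 0.5 at half-saturation
#' @export
log_gain <- function(x, f, K, n) {
  check_hill_params(f, K, n)
  if (any(!is.finite(x) | x <= 0)) {
    abort("`x` must be finite and positive.", class = "ergnet_invalid_parameter")
  }
  u <- (x / K)^n
  n * u * (f - 1) / ((1 + u) * (1 + f * u))
}
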