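#' Model parameters of the dimensionless two-gene network
#'
#' Container for the kinetic parameters of the normalized ERalpha (`e`) and
#' GATA3 (`g`) protein equations
#' \deqn{de/dt = b_e F_1(e) F_2(g) - k_e e, \qquad
#'       dg/dt = b_g F_3(e) F_4(g) - k_g g,}
#' where each \eqn{F_j} is a [hill_fold()] regulation function. Concentrations
#' are normalized by the unperturbed wild-type levels, so `b_e`, `b_g`, `K_j`
#' are dimensionless and `k_e`, `k_g` carry units of 1/hour.
#'
#' @param b_e,b_g Basal synthesis rates (dimensionless, > 0). Usually set by
#'   [normalize_to_wt()] rather than by hand.
#' @param k_e,k_g First-order degradation (plus dilution) rates, per hour.
#' @param f Fold changes `c(f1, f2, f3, f4)` of the four links (> 0).
#' @param K Half-saturation levels `c(K1, ..., K4)` in normalized units (> 0).
#' @param n Effective cooperativities `c(n1, ..., n4)` (>= 1).
#' @return An object of class `ergnet_params`.
#' @seealso [normalize_to_wt()], [topology()]
#' @export
model_params <- function(b_e = 0.3, b_g = 0.25, k_e = 0.3, k_g = 0.25,
                         f = c(1, 3, 0.5, 4), K = rep(1, 4), n = rep(2, 4)) {
  p <- structure(
    list(b_e = as.numeric(b_e), b_g = as.numeric(b_g),
         k_e = as.numeric(k_e), k_g = as.numeric(k_g),
         f = setNames(as.numeric(f), LINKS),
         K = setNames(as.numeric(K), LINKS),
         n = setNames(as.numeric(n), LINKS)),
    class = "ergnet_params")
  validate_params(p)
  p
}

validate_params <- function(p, topology = NULL) {
  vals <- c(p$b_e, p$b_g, p$k_e, p$k_g, p$f, p$K)
  if (any(!is.finite(vals) | vals <= 0) || any(!is.finite(p$n) | p$n < 1)) {
    abort("All parameters must be finite and positive, with n >= 1.",
          class = "ergnet_invalid_parameter")
  }
  if (!is.null(topology)) {
    topology <- as_topology(topology)
    for (j in seq_along(LINKS)) {
      rng <- switch(topology[[j]], "+" = p$f[j] > 1, "-" = p$f[j] < 1,
                    "0" = p$f[j] == 1)
      if (!rng) {
        abort(sprintf("Fold change f%d = %.4g violates the '%s' sign of link %s.",
                      j, p$f[j], topology[[j]], LINKS[j]),
              class = "ergnet_invalid_parameter")
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.ergnet_params <- function(x, ...) {
  cat("Two-gene network parameters (normalized units)\n")
  cat(sprintf("  synthesis  b_e = %.4g, b_g = %.4g\n", x$b_e, x$b_g))
  cat(sprintf("  turnover   k_e = %.4g /h, k_g = %.4g /h (half-lives %.2g, %.2g h)\n",
              x$k_e, x$k_g, log(2) / x$k_e, log(2) / x$k_g))
  m <- rbind(f = x$f, K = x$K, n = x$n)
  print(round(m, 4))
  invisible(x)
}

#' Impose the wild-type normalization constraint
#'
#' Rescales the basal synthesis rates so that the unperturbed steady state is
#' exactly `(e, g) = (1, 1)`: `b_e = k_e / (F1(1) F2(1))` and
#' `b_g = k_g / (F3(1) F4(1))`. This encodes the normalization of
#' concentrations by their unperturbed wild-type values and removes `b_e`,
#' `b_g` as free parameters. Idempotent; all other parameters are unchanged.
#'
#' @param params An [model_params()] object.
#' @param topology Optional [topology()]; if supplied, the fold-change signs
#'   are validated against it first.
#' @return The rescaled `ergnet_params` object.
#' @export
normalize_to_wt <- function(params, topology = NULL) {
  validate_params(params, topology)
  F1 <- hill_fold(1, params$f[1], params$K[1], params$n[1])
  F2 <- hill_fold(1, params$f[2], params$K[2], params$n[2])
  F3 <- hill_fold(1, params$f[3], params$K[3], params$n[3])
  F4 <- hill_fold(1, params$f[4], params$K[4], params$n[4])
  params$b_e <- unname(params$k_e / (F1 * F2))
  params$b_g <- unname(params$k_g / (F3 * F4))
  params
}

# pack parameters into the fixed-layout numeric vector consumed by src/core.cpp
theta_vec <- function(p) {
  c(p$b_e, p$b_g, p$k_e, p$k_g, unname(p$f), unname(p$K), unname(p$n))
}

theta_to_params <- function(theta) {
  theta <- unname(theta)
  structure(
    list(b_e = theta[1], b_g = theta[2], k_e = theta[3], k_g = theta[4],
         f = setNames(theta[5:8], LINKS), K = setNames(theta[9:12], LINKS),
         n = setNames(theta[13:16], LINKS)),
    class = "ergnet_params")
}

#' Implied sign topology of a parameter set
#'
#' @param params An [model_params()] object.
#' @return The [topology()] implied by the fold changes (`f > 1` positive,
#'   `f < 1` negative, `f = 1` null).
#' @export
implied_topology <- function(params) {
  s <- sign_of_fold(params$f)
  topology(s[1], s[2], s[3], s[4])
}
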