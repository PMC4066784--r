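#' Stochastic version of the network model
#'
#' Wraps a deterministic parameter set with a system size `omega`, the scale
#' converting normalized concentration 1.0 into `omega` molecules. The
#' corresponding chemical master equation has four reaction channels — one
#' birth and one death channel per protein, with birth propensity
#' `omega x` (deterministic synthesis term) — the minimal scheme whose
#' macroscopic limit is the deterministic model.
#'
#' @param params [model_params()].
#' @param topology Optional [topology()] for sign validation.
#' @param omega System size (> 0). Default 500; use [calibrate_omega()] to
#'   match measured control-condition noise instead.
#' @return An object of class `ergnet_system`.
#' @export
stochastic_system <- function(params, topology = NULL, omega = 500) {
  validate_params(params, topology)
  if (!is.finite(omega) || omega <= 0) {
    abort("`omega` must be positive.", class = "ergnet_config_error")
  }
  structure(list(params = params, omega = omega), class = "ergnet_system")
}

#' @export
print.ergnet_system <- function(x, ...) {
  cat(sprintf("Stochastic two-gene system, omega = %g molecules per unit level\n",
              x$omega))
  print(x$params)
  invisible(x)
}

new_noise_summary <- function(mean, cvs, covariance, method, extra = list()) {
  mean <- unname(mean); cvs <- unname(cvs)
  structure(c(list(mean_e = mean[1], mean_g = mean[2], cv_e = cvs[1],
                   cv_g = cvs[2], covariance = covariance, method = method),
              extra),
            class = "ergnet_noise")
}

#' @export
print.ergnet_noise <- function(x, ...) {
  cat(sprintf("Noise summary (%s): mean e = %.4g, g = %.4g; CV e = %.4g, g = %.4g\n",
              x$method, x$mean_e, x$mean_g, x$cv_e, x$cv_g))
  invisible(x)
}

#' Intrinsic noise by the Linear Noise Approximation
#'
#' Linearizes the chemical master equation of the system at its stable fixed
#' point: with Jacobian `A` and diffusion matrix `D` (channel propensities
#' evaluated at the fixed point, scaled to normalized-concentration units),
#' the stationary covariance `C` solves the continuous Lyapunov equation
#' `A C + C A' + D = 0`. Noise is reported as the coefficient of variation
#' CV = sigma/mu per species. For an all-null topology each species is an
#' independent birth-death process and the LNA reproduces the Poisson law
#' `CV^2 = 1/(omega * mean)` exactly.
#'
#' @param system [stochastic_system()].
#' @param condition [perturbation()].
#' @return An `ergnet_noise` object with stationary means (normalized
#'   units), CVs and the 2x2 covariance matrix.
#' @export
lna_noise <- function(system, condition = perturbation()) {
  p <- system$params
  omega <- system$omega
  st <- stable_state(p, condition)
  if (nrow(st$stable) == 0 || st$multistable) {
    abort("LNA requires a unique stable fixed point under this condition.",
          class = "ergnet_lna_invalid")
  }
  e <- st$stable$e[1]; g <- st$stable$g[1]
  sc <- cond_scalars(condition)
  A <- jacobian_at(e, g, p, sc)
  if (max(Re(eigen(A, only.values = TRUE)$values)) >= 0) {
    abort("Jacobian not stable; LNA invalid.", class = "ergnet_lna_invalid")
  }
  # diffusion: birth + death propensities per species, over omega
  prod_e <- sc$se * p$b_e *
    hill_fold(e * sc$ici_act, p$f[1], p$K[1], p$n[1]) *
    hill_fold(g, p$f[2], p$K[2], p$n[2])
  prod_g <- sc$sg * p$b_g *
    hill_fold(e * sc$ici_act, p$f[3], p$K[3], p$n[3]) *
    hill_fold(g, p$f[4], p$K[4], p$n[4])
  D <- diag(c(prod_e + (p$k_e + sc$k_loss) * e, prod_g + p$k_g * g)) / omega
  C <- solve_lyapunov_2x2(A, D)
  cvs <- sqrt(diag(C)) / c(e, g)
  new_noise_summary(c(e, g), cvs, C, "lna")
}

# A C + C A' + D = 0 for symmetric 2x2 C: linear system in (c11, c12, c22)
solve_lyapunov_2x2 <- function(A, D) {
  M <- rbind(c(2 * A[1, 1], 2 * A[1, 2], 0),
             c(A[2, 1], A[1, 1] + A[2, 2], A[1, 2]),
             c(0, 2 * A[2, 1], 2 * A[2, 2]))
  x <- solve(M, -c(D[1, 1], D[1, 2], D[2, 2]))
  C <- matrix(c(x[1], x[2], x[2], x[3]), 2,
              dimnames = list(SPECIES, SPECIES))
  C
}

#' Exact stochastic simulation of the network
#'
#' Gillespie direct-method simulation of the four reaction channels in
#' molecule counts, used as the independent oracle validating [lna_noise()].
#' Stationary CVs are estimated from samples taken on a regular grid after a
#' burn-in (first `burn_frac` of the simulated span is discarded), with
#' standard errors from contiguous batch means.
#'
#' @param system [stochastic_system()].
#' @param condition [perturbation()].
#' @param t_end Simulated span, hours.
#' @param seed Integer seed (R RNG; identical seeds give identical paths).
#' @param sample_dt Sampling interval, hours.
#' @param init Initial normalized levels; default the stable fixed point.
#' @param burn_frac Fraction of the span discarded as burn-in.
#' @param n_batches Number of batches for standard errors.
#' @return An object of class `ergnet_ssa`: list with `samples` (tibble:
#'   `time_h`, `e_count`, `g_count`) and `summary` (tibble: `species`,
#'   `mean` normalized, `cv`, `cv_se`).
#' @export
gillespie_sim <- function(system, condition = perturbation(), t_end = 2000,
                          seed = 1, sample_dt = 0.5, init = NULL,
                          burn_frac = 0.2, n_batches = 50) {
  p <- system$params
  omega <- system$omega
  in_chx <- FALSE
  if (!is.null(condition$chx_window)) {
    if (condition$chx_window[1] > 0 || condition$chx_window[2] < t_end) {
      abort("Stochastic simulation supports cycloheximide only over the full span.",
            class = "ergnet_config_error")
    }
    in_chx <- TRUE
  }
  sc <- cond_scalars(condition, in_chx)
  if (is.null(init)) {
    y <- steady_state_from(p, condition)
    if (is.null(y)) {
      st <- stable_state(p, condition)$stable
      if (nrow(st) == 0) abort("No stable state to initialize from.",
                               class = "ergnet_search_failure")
      y <- c(st$e[1], st$g[1])
    }
    init <- y
  }
  set.seed(seed)
  m <- gillespie_cpp(theta_vec(p), sc$se, sc$sg, sc$ici_act, sc$k_loss,
                     omega, round(init * omega), 0, t_end, sample_dt)
  samples <- tibble::tibble(time_h = m[, 1], e_count = m[, 2],
                            g_count = m[, 3])
  post <- samples[samples$time_h >= burn_frac * t_end, ]
  summ <- purrr::map_dfr(list(er = post$e_count, gata3 = post$g_count),
                         batch_cv, n_batches = n_batches, .id = "species")
  summ$mean <- summ$mean / omega
  structure(list(samples = samples, summary = summ, omega = omega,
                 seed = seed),
            class = "ergnet_ssa")
}

batch_cv <- function(x, n_batches = 50) {
  cv <- sd(x) / mean(x)
  if (length(x) < 4) {
    return(tibble::tibble(mean = mean(x), cv = cv, cv_se = NA_real_))
  }
  nb <- max(2, min(n_batches, floor(length(x) / 2)))
  bid <- cut(seq_along(x), nb, labels = FALSE)
  bcv <- vapply(split(x, bid), function(b) sd(b) / mean(b), numeric(1))
  tibble::tibble(mean = mean(x), cv = cv,
                 cv_se = sd(bcv) / sqrt(nb))
}

#' @export
print.ergnet_ssa <- function(x, ...) {
  cat(sprintf("Gillespie simulation (omega = %g, seed = %d):\n", x$omega,
              x$seed))
  print(x$summary)
  invisible(x)
}

#' Remove a regulatory link under controlled comparison
#'
#' Sets the link's fold change to 1 and rescales the basal production rate
#' of the regulated gene by the removed factor's value at the pre-removal
#' stationary state, so the deterministic means of both species are
#' unchanged. This isolates the link's effect on noise from its effect on
#' expression level — the controlled comparison used to show that breaking
#' either cross-link of the negative feedback raises the noise of exactly
#' one species.
#'
#' @param system [stochastic_system()].
#' @param link Link name to remove.
#' @param condition Condition defining the reference stationary state
#'   (default unperturbed).
#' @return The modified `ergnet_system`.
#' @export
remove_link_controlled <- function(system, link = "gata3_to_er",
                                   condition = perturbation()) {
  j <- match(match.arg(link, LINKS), LINKS)
  p <- system$params
  st <- stable_state(p, condition)$stable
  if (nrow(st) == 0) {
    abort("No stable stationary state to match.",
          class = "ergnet_adjustment_failure")
  }
  e0 <- st$e[1]; g0 <- st$g[1]
  x0 <- if (j %in% c(1, 3)) e0 else g0
  factor_old <- unname(hill_fold(x0, p$f[j], p$K[j], p$n[j]))
  p$f[j] <- 1
  if (j %in% c(1, 2)) p$b_e <- p$b_e * factor_old else p$b_g <- p$b_g * factor_old
  # the old fixed point is preserved by construction; verify it is still there
  y <- steady_state_from(p, condition, seed_state = c(e0, g0))
  if (is.null(y) || max(abs(y - c(e0, g0))) > 1e-6) {
    abort("Stationary mean could not be matched after link removal.",
          class = "ergnet_adjustment_failure")
  }
  stochastic_system(p, omega = system$omega)
}

#' Extrinsic (parameter) noise by ensemble propagation
#'
#' Cell-to-cell variability in kinetic rates is emulated by sampling the
#' synthesis and degradation rates (`b_e`, `b_g`, `k_e`, `k_g`) from
#' independent mean-preserving lognormal distributions with a shared CV,
#' solving the deterministic steady state of every sampled cell and
#' summarizing the ensemble of steady-state levels.
#'
#' @param system [stochastic_system()] (omega is irrelevant here).
#' @param condition [perturbation()].
#' @param parameter_cv Coefficient of variation of the rate distributions,
#'   in (0, 0.5].
#' @param n_samples Ensemble size (>= 100).
#' @param seed Integer seed.
#' @param vary Which rates to vary (default all four).
#' @return An `ergnet_noise` object (method `"extrinsic"`), with the number
#'   of failed steady-state solves recorded as `n_failed`.
#' @export
extrinsic_noise <- function(system, condition = perturbation(),
                            parameter_cv = 0.1, n_samples = 1000, seed = 1,
                            vary = c("b_e", "b_g", "k_e", "k_g")) {
  if (parameter_cv <= 0 || parameter_cv > 0.5) {
    abort("`parameter_cv` must lie in (0, 0.5].", class = "ergnet_config_error")
  }
  if (n_samples < 100) {
    abort("`n_samples` must be >= 100.", class = "ergnet_config_error")
  }
  p0 <- system$params
  s <- sqrt(log1p(parameter_cv^2))
  set.seed(seed)
  draws <- matrix(rlnorm(n_samples * length(vary), meanlog = -s^2 / 2,
                         sdlog = s),
                  nrow = n_samples, dimnames = list(NULL, vary))
  states <- matrix(NA_real_, n_samples, 2)
  for (i in seq_len(n_samples)) {
    p <- p0
    for (v in vary) p[[v]] <- p0[[v]] * draws[i, v]
    y <- steady_state_from(p, condition)
    if (!is.null(y)) states[i, ] <- y
  }
  ok <- stats::complete.cases(states)
  if (mean(!ok) > 0.10) {
    abort("More than 10% of parameter samples lack a stable steady state.",
          class = "ergnet_unreliable_ensemble")
  }
  states <- states[ok, , drop = FALSE]
  mu <- colMeans(states)
  C <- stats::cov(states)
  dimnames(C) <- list(SPECIES, SPECIES)
  new_noise_summary(mu, sqrt(diag(C)) / mu, C, "extrinsic",
                    extra = list(n_failed = sum(!ok), n_used = sum(ok)))
}

#' Calibrate the system size to measured noise
#'
#' LNA CVs scale exactly as `1/sqrt(omega)`, so matching model noise to
#' CVs measured under a control condition is a one-dimensional problem with
#' a closed-form least-squares solution; the result is clamped to `bounds`.
#' For an all-null topology with a single target this reduces to the
#' Poisson inversion `omega = 1/(cv^2 * mean)`.
#'
#' @param system [stochastic_system()] (its omega is ignored).
#' @param target_cvs Named numeric of measured CVs, e.g.
#'   `c(er = 0.3, gata3 = 0.25)`; a subset of species is allowed.
#' @param condition Control condition under which the CVs were measured.
#' @param bounds Allowed omega range.
#' @param warn_threshold Relative residual mismatch above which a
#'   calibration warning is raised.
#' @return The calibrated omega (numeric scalar).
#' @export
calibrate_omega <- function(system, target_cvs, condition = perturbation(),
                            bounds = c(1, 1e7), warn_threshold = 0.5) {
  if (any(target_cvs <= 0)) {
    abort("`target_cvs` must be positive.", class = "ergnet_config_error")
  }
  ref <- lna_noise(stochastic_system(system$params, omega = 1), condition)
  a <- c(er = ref$cv_e, gata3 = ref$cv_g)[names(target_cvs)]
  if (any(is.na(a))) {
    abort("`target_cvs` names must be 'er' and/or 'gata3'.",
          class = "ergnet_config_error")
  }
  # cv_i(omega) = a_i / sqrt(omega); least squares in s = 1/sqrt(omega)
  s_opt <- sum(a * target_cvs) / sum(a^2)
  omega <- min(max(1 / s_opt^2, bounds[1]), bounds[2])
  resid <- sqrt(sum((a / sqrt(omega) - target_cvs)^2) / sum(target_cvs^2))
  if (resid > warn_threshold) {
    warn(sprintf(
      "Calibration mismatch: relative residual %.2f exceeds %.2f within bounds.",
      resid, warn_threshold))
  }
  omega
}
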