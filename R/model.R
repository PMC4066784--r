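#' Right-hand side of the two-gene network ODE
#'
#' Reference (pure R) evaluation of the time derivatives
#' \deqn{de/dt = s_e b_e F_1(e_{act}) F_2(g) - (k_e + k_{loss}) e, \qquad
#'       dg/dt = s_g b_g F_3(e_{act}) F_4(g) - k_g g,}
#' where `s_e`, `s_g` are the siRNA synthesis scalings of the condition
#' (both zero inside a cycloheximide window) and `e_act` is the ICI-reduced
#' active ERalpha level. Regulatory links combine multiplicatively. The
#' compiled integrator in [simulate_network()] evaluates the identical
#' expressions; this function exists for direct inspection, Jacobians and
#' cross-checks.
#'
#' @param state Named numeric `c(e = , g = )`, normalized protein levels.
#' @param params [model_params()].
#' @param topology Optional [topology()] used to validate sign constraints.
#' @param condition [perturbation()].
#' @param time Time in hours (used only to decide whether the cycloheximide
#'   window is active).
#' @return Named numeric `c(e = de/dt, g = dg/dt)`.
#' @export
derivatives <- function(state, params, topology = NULL,
                        condition = perturbation(), time = 0) {
  validate_params(params, topology)
  in_chx <- !is.null(condition$chx_window) &&
    time >= condition$chx_window[1] && time < condition$chx_window[2]
  sc <- cond_scalars(condition, in_chx)
  e <- max(state[["e"]], 0); g <- max(state[["g"]], 0)
  ea <- e * sc$ici_act
  F1 <- hill_fold(ea, params$f[1], params$K[1], params$n[1])
  F2 <- hill_fold(g, params$f[2], params$K[2], params$n[2])
  F3 <- hill_fold(ea, params$f[3], params$K[3], params$n[3])
  F4 <- hill_fold(g, params$f[4], params$K[4], params$n[4])
  c(e = unname(sc$se * params$b_e * F1 * F2 - (params$k_e + sc$k_loss) * state[["e"]]),
    g = unname(sc$sg * params$b_g * F3 * F4 - params$k_g * state[["g"]]))
}

# Jacobian of the deterministic system at (e, g) under constant scalars
jacobian_at <- function(e, g, p, sc) {
  ea <- e * sc$ici_act
  F1 <- hill_fold(ea, p$f[1], p$K[1], p$n[1])
  F2 <- hill_fold(g, p$f[2], p$K[2], p$n[2])
  F3 <- hill_fold(ea, p$f[3], p$K[3], p$n[3])
  F4 <- hill_fold(g, p$f[4], p$K[4], p$n[4])
  dF1 <- hill_fold_deriv(ea, p$f[1], p$K[1], p$n[1]) * sc$ici_act
  dF2 <- hill_fold_deriv(g, p$f[2], p$K[2], p$n[2])
  dF3 <- hill_fold_deriv(ea, p$f[3], p$K[3], p$n[3]) * sc$ici_act
  dF4 <- hill_fold_deriv(g, p$f[4], p$K[4], p$n[4])
  matrix(c(sc$se * p$b_e * dF1 * F2 - (p$k_e + sc$k_loss),
           sc$se * p$b_e * F1 * dF2,
           sc$sg * p$b_g * dF3 * F4,
           sc$sg * p$b_g * F3 * dF4 - p$k_g),
         nrow = 2, byrow = TRUE,
         dimnames = list(SPECIES, SPECIES))
}

# Fast path: integrate under a condition, restarting at cycloheximide window
# boundaries. Returns a length(times) x 2 matrix (columns e, g).
sim_matrix <- function(theta, condition, times, init = c(1, 1),
                       rtol = 1e-8, atol = 1e-10) {
  t0 <- times[1]
  win <- condition$chx_window
  bounds <- if (is.null(win)) numeric(0) else win
  cuts <- sort(unique(c(t0, bounds[bounds > t0 & bounds < max(times)],
                        max(times))))
  out <- matrix(NA_real_, length(times), 2)
  y <- init
  for (i in seq_len(length(cuts) - 1)) {
    a <- cuts[i]; b <- cuts[i + 1]
    in_chx <- !is.null(win) && a >= win[1] && a < win[2]
    sc <- cond_scalars(condition, in_chx)
    sel <- which(times > a - 1e-12 & times <= b + 1e-12)
    seg_times <- unique(c(times[sel], b))
    m <- ode_segment_cpp(theta, sc$se, sc$sg, sc$ici_act, sc$k_loss,
                         y, a, seg_times, rtol, atol)
    if (length(sel)) out[sel, ] <- m[match(times[sel], seg_times), , drop = FALSE]
    y <- m[nrow(m), ]
  }
  if (times[1] <= cuts[1] + 1e-12) out[1, ] <- init
  colnames(out) <- SPECIES
  out
}

#' Simulate the network under a perturbation condition
#'
#' Integrates the two-gene ODE with an adaptive embedded Runge-Kutta 4(5)
#' scheme (Cash-Karp pairs, relative tolerance `rtol`), restarting the
#' integration at every cycloheximide window boundary so the discontinuity
#' in synthesis never crosses a step. Trajectories from non-negative initial
#' conditions remain non-negative.
#'
#' @param params [model_params()].
#' @param topology Optional [topology()] for sign validation.
#' @param condition [perturbation()].
#' @param times Strictly increasing vector of output times, hours. The first
#'   entry is the initial time.
#' @param init Initial state `c(e, g)`, non-negative. Default wild type
#'   `c(1, 1)`.
#' @param rtol,atol Integrator tolerances.
#' @return A tibble with columns `time_h`, `species` (`"er"`/`"gata3"`),
#'   `level` and `condition` (a compact label).
#' @examples
#' gt <- default_ground_truth()
#' simulate_network(gt$params, gt$topology, perturbation("gata3", 0.9),
#'                  times = seq(0, 48, by = 4))
#' @export
simulate_network <- function(params, topology = NULL,
                             condition = perturbation(),
                             times = seq(0, 48, by = 1), init = c(1, 1),
                             rtol = 1e-8, atol = 1e-10) {
  validate_params(params, topology)
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing.", class = "ergnet_config_error")
  }
  if (any(init < 0)) {
    abort("`init` must be non-negative.", class = "ergnet_config_error")
  }
  m <- sim_matrix(theta_vec(params), condition, times, init, rtol, atol)
  tibble::tibble(
    time_h = rep(times, 2),
    species = rep(SPECIES, each = length(times)),
    level = c(m[, 1], m[, 2]),
    condition = condition_label(condition)
  )
}

condition_label <- function(cond) {
  base <- switch(cond$sirna_target, none = "control", er = "si_er",
                 gata3 = "si_gata3")
  if (!is.null(cond$chx_window)) base <- paste0(base, "+chx")
  if (cond$ici_dose > 0) base <- paste0(base, "+ici", cond$ici_dose)
  base
}

#' Steady-state mRNA proxy for ERalpha
#'
#' The model tracks proteins only; the ERalpha mRNA readout (qPCR-style) is
#' proxied by the normalized transcriptional production term
#' `b_e F1(e_active) F2(g)` divided by its wild-type value, i.e.
#' quasi-steady-state mRNA proportional to the transcription rate.
#'
#' @param state Named numeric `c(e = , g = )`.
#' @param params [model_params()].
#' @param condition [perturbation()] (supplies the ICI activity factor).
#' @return Dimensionless proxy, equal to 1 at the unperturbed wild type of a
#'   [normalize_to_wt()] parameter set.
#' @export
mrna_proxy <- function(state, params, condition = perturbation()) {
  sc <- cond_scalars(condition)
  ea <- max(state[["e"]], 0) * sc$ici_act
  num <- params$b_e *
    hill_fold(ea, params$f[1], params$K[1], params$n[1]) *
    hill_fold(max(state[["g"]], 0), params$f[2], params$K[2], params$n[2])
  den <- params$b_e *
    hill_fold(1, params$f[1], params$K[1], params$n[1]) *
    hill_fold(1, params$f[2], params$K[2], params$n[2])
  unname(num / den)
}
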