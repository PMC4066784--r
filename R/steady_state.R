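#' Locate steady states of the perturbed network
#'
#' Deterministic grid-seeded Newton search for all non-negative fixed points
#' of the two-gene system under a perturbation condition. Newton iterations
#' with the analytic Jacobian are run (vectorized) from an
#' `n_grid` x `n_grid` seed lattice over the bounding box; converged roots
#' are deduplicated within `dedup_tol` per coordinate and classified
#' stable/unstable by the real parts of the Jacobian eigenvalues.
#'
#' The inferred negative-feedback network is monostable in the high-ERalpha /
#' high-GATA3 state for best-fit-like parameter sets; this function is also
#' the basis of the dose-response and noise analyses, which require the
#' stable fixed point under each condition.
#'
#' @param params [model_params()].
#' @param topology Optional [topology()] for sign validation.
#' @param condition [perturbation()]. A cycloheximide window is ignored here
#'   (steady states are only meaningful outside it); siRNA and ICI apply.
#' @param box Upper corner of the square search box `[0, box]^2`.
#' @param n_grid Seeds per axis.
#' @param dedup_tol Deduplication tolerance per coordinate.
#' @return A tibble with columns `e`, `g`, `stable` (logical) and
#'   `eigen_max` (largest real part), ordered by `e`.
#' @examples
#' gt <- default_ground_truth()
#' steady_states(gt$params, gt$topology)  # single stable point at (1, 1)
#' @export
steady_states <- function(params, topology = NULL, condition = perturbation(),
                          box = 10, n_grid = 25, dedup_tol = 1e-6) {
  validate_params(params, topology)
  sc <- cond_scalars(condition, in_chx = FALSE)
  seeds <- unname(as.matrix(expand.grid(seq(0, box, length.out = n_grid),
                                        seq(0, box, length.out = n_grid))))
  pts <- newton_batch(seeds, params, sc, box)
  if (nrow(pts) == 0) {
    abort("No fixed point found in the search box; enlarge `box`.",
          class = "ergnet_search_failure")
  }
  # deduplicate (roots are machine-precision converged, so sorting is safe)
  o <- order(pts[, 1], pts[, 2])
  pts <- pts[o, , drop = FALSE]
  if (nrow(pts) > 1) {
    keep <- rep(TRUE, nrow(pts))
    for (i in 2:nrow(pts)) {
      dup <- vapply(which(keep[seq_len(i - 1)]), function(k) {
        all(abs(pts[i, ] - pts[k, ]) < dedup_tol)
      }, logical(1))
      if (any(dup)) keep[i] <- FALSE
    }
    pts <- pts[keep, , drop = FALSE]
  }
  res <- purrr::map_dfr(seq_len(nrow(pts)), function(i) {
    A <- jacobian_at(pts[i, 1], pts[i, 2], params, sc)
    lam <- max(Re(eigen(A, only.values = TRUE)$values))
    tibble::tibble(e = pts[i, 1], g = pts[i, 2],
                   stable = lam < 0, eigen_max = lam)
  })
  dplyr::arrange(res, .data$e)
}

# unchecked vectorized Hill evaluations for inner loops
hill_vec <- function(x, f, K, n) {
  u <- (pmax(x, 0) / K)^n
  (1 + f * u) / (1 + u)
}

hill_vec_deriv <- function(x, f, K, n) {
  if (f == 1) return(numeric(length(x)))
  xp <- pmax(x, 0)
  u <- (xp / K)^n
  out <- numeric(length(x))
  pos <- xp > 0
  out[pos] <- (f - 1) * n * u[pos] / (xp[pos] * (1 + u[pos])^2)
  if (any(!pos) && n == 1) out[!pos] <- (f - 1) / K
  out
}

# rhs and Jacobian entries for a batch of states (vectors E, G)
rhs_jac_batch <- function(E, G, p, sc) {
  ea <- pmax(E, 0) * sc$ici_act
  g <- pmax(G, 0)
  F1 <- hill_vec(ea, p$f[1], p$K[1], p$n[1])
  F2 <- hill_vec(g, p$f[2], p$K[2], p$n[2])
  F3 <- hill_vec(ea, p$f[3], p$K[3], p$n[3])
  F4 <- hill_vec(g, p$f[4], p$K[4], p$n[4])
  dF1 <- hill_vec_deriv(ea, p$f[1], p$K[1], p$n[1]) * sc$ici_act
  dF2 <- hill_vec_deriv(g, p$f[2], p$K[2], p$n[2])
  dF3 <- hill_vec_deriv(ea, p$f[3], p$K[3], p$n[3]) * sc$ici_act
  dF4 <- hill_vec_deriv(g, p$f[4], p$K[4], p$n[4])
  ke <- p$k_e + sc$k_loss
  list(fe = sc$se * p$b_e * F1 * F2 - ke * E,
       fg = sc$sg * p$b_g * F3 * F4 - p$k_g * G,
       J11 = sc$se * p$b_e * dF1 * F2 - ke,
       J12 = sc$se * p$b_e * F1 * dF2,
       J21 = sc$sg * p$b_g * dF3 * F4,
       J22 = sc$sg * p$b_g * F3 * dF4 - p$k_g)
}

# vectorized Newton over a seed matrix; returns matrix of converged roots
newton_batch <- function(seeds, p, sc, box, tol = 1e-12, maxit = 80) {
  E <- seeds[, 1]; G <- seeds[, 2]
  alive <- rep(TRUE, length(E))
  for (it in seq_len(maxit)) {
    r <- rhs_jac_batch(E, G, p, sc)
    conv <- abs(r$fe) < tol & abs(r$fg) < tol
    if (all(conv | !alive)) break
    det <- r$J11 * r$J22 - r$J12 * r$J21
    se <- (-r$J22 * r$fe + r$J12 * r$fg) / det
    sg <- (r$J21 * r$fe - r$J11 * r$fg) / det
    upd <- alive & !conv
    E[upd] <- E[upd] + se[upd]
    G[upd] <- G[upd] + sg[upd]
    bad <- !is.finite(E) | !is.finite(G) | E < -0.5 | G < -0.5 |
      E > 3 * box | G > 3 * box
    alive <- alive & !bad
    E[!alive] <- 0; G[!alive] <- 0
  }
  r <- rhs_jac_batch(E, G, p, sc)
  ok <- alive & abs(r$fe) < tol & abs(r$fg) < tol &
    E > -1e-9 & G > -1e-9 & E <= box * 1.5 & G <= box * 1.5
  cbind(pmax(E[ok], 0), pmax(G[ok], 0))
}

# single stable fixed point or informative error; helper for LNA / dose-response
stable_state <- function(params, condition = perturbation(), box = 10,
                         n_grid = 25) {
  ss <- steady_states(params, condition = condition, box = box, n_grid = n_grid)
  st <- dplyr::filter(ss, .data$stable)
  list(all = ss, stable = st, multistable = nrow(st) > 1)
}

# cheap path used in ensembles: Newton from a single seed; returns a STABLE
# root or NULL (no global search)
steady_state_from <- function(p, condition, seed_state = c(1, 1), box = 10) {
  sc <- cond_scalars(condition, in_chx = FALSE)
  pts <- newton_batch(matrix(seed_state, 1), p, sc, box)
  if (nrow(pts) == 0) return(NULL)
  y <- pts[1, ]
  A <- jacobian_at(y[1], y[2], p, sc)
  if (max(Re(eigen(A, only.values = TRUE)$values)) >= 0) return(NULL)
  y
}
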