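#' Weighted least-squares error of a parameter set against time-course data
#'
#' The fit error E is the sum over all observations of squared residuals
#' between simulated and observed normalized levels, each residual divided
#' by `max(sd, sd_floor)` — a chi-square-like objective in which poorly
#' replicated points cannot dominate through vanishing standard deviations.
#' Depletion phases are simulated from the wild-type state `(1, 1)`;
#' recovery phases from the post-cycloheximide state under continued siRNA.
#' Integration failures yield a large finite penalty (`1e6`) rather than an
#' exception so multi-start optimization can continue.
#'
#' @param data Tidy observation table with columns `condition`
#'   (`"control"`, `"si_er"`, `"si_gata3"`), `phase` (`"depletion"` /
#'   `"recovery"`), `time_h`, `species` (`"er"` / `"gata3"`), `level`, `sd`.
#' @param params [model_params()].
#' @param topology Optional [topology()] for sign validation.
#' @param sd_floor Lower bound applied to observation standard deviations.
#' @param sirna_efficiency Knockdown efficiency assumed for the experiments.
#' @param t_sirna,t_chx Durations (hours) of the siRNA incubation and
#'   cycloheximide window preceding the recovery phase.
#' @return The scalar error E (>= 0).
#' @export
fit_error <- function(data, params, topology = NULL, sd_floor = 0.05,
                      sirna_efficiency = 0.9, t_sirna = 48, t_chx = 15) {
  validate_params(params, topology)
  design <- prepare_design(data, sd_floor, sirna_efficiency, t_sirna, t_chx)
  r <- design_residuals(theta_vec(params), design)
  sum(r^2)
}

# Precompute per-(condition, phase) blocks: observation times, target levels,
# weights and index maps, so the optimizer's objective does no data wrangling.
prepare_design <- function(data, sd_floor = 0.05, sirna_efficiency = 0.9,
                           t_sirna = 48, t_chx = 15) {
  req <- c("condition", "phase", "time_h", "species", "level", "sd")
  if (!all(req %in% names(data))) {
    abort(paste("Data must contain columns:", paste(req, collapse = ", ")),
          class = "ergnet_config_error")
  }
  bad <- setdiff(unique(data$condition), c("control", "si_er", "si_gata3"))
  if (length(bad)) {
    abort(paste0("Unknown condition label(s): ", paste(bad, collapse = ", ")),
          class = "ergnet_config_error")
  }
  blocks <- list()
  grp <- dplyr::group_split(dplyr::group_by(data, .data$condition, .data$phase))
  for (d in grp) {
    cond_label <- d$condition[1]
    target <- switch(cond_label, control = "none", si_er = "er",
                     si_gata3 = "gata3")
    cond <- perturbation(target, sirna_efficiency)
    times <- sort(unique(d$time_h))
    idx <- cbind(match(d$time_h, times), match(d$species, SPECIES))
    blocks[[length(blocks) + 1]] <- list(
      phase = d$phase[1], cond = cond, sc = cond_scalars(cond),
      times = times, idx = idx, obs = d$level,
      w = 1 / pmax(d$sd, sd_floor))
  }
  list(blocks = blocks, t_sirna = t_sirna, t_chx = t_chx, penalty = 1e6)
}

# weighted residual vector for a packed parameter vector
design_residuals <- function(theta, design) {
  res <- lapply(design$blocks, function(b) {
    m <- tryCatch({
      if (b$phase == "depletion") {
        ode_segment_cpp(theta, b$sc$se, b$sc$sg, b$sc$ici_act, b$sc$k_loss,
                        c(1, 1), 0, b$times)
      } else {
        sim_recovery_matrix(theta, b$cond, b$times, design$t_sirna,
                            design$t_chx)
      }
    }, error = function(e) NULL)
    if (is.null(m) || any(!is.finite(m))) {
      return(rep(sqrt(design$penalty / length(b$obs)), length(b$obs)))
    }
    (m[b$idx] - b$obs) * b$w
  })
  unlist(res, use.names = FALSE)
}

#' Estimate degradation rates from the cycloheximide decay
#'
#' Under translation block the proteins decay as pure first-order processes,
#' so the ratio between the recovery-phase initial level (immediately after
#' the `t_chx`-hour cycloheximide window) and the depletion level at
#' `t_sirna` identifies `k = -log(ratio) / t_chx` per species independently
#' of any regulatory parameter. Ratios are pooled geometrically across
#' conditions.
#'
#' @inheritParams fit_error
#' @return Named numeric `c(er = k_e, gata3 = k_g)` in 1/hour.
#' @export
estimate_degradation_rates <- function(data, t_sirna = 48, t_chx = 15) {
  dep <- dplyr::filter(data, .data$phase == "depletion",
                       .data$time_h == t_sirna)
  rec <- dplyr::filter(data, .data$phase == "recovery", .data$time_h == 0)
  j <- dplyr::inner_join(dep, rec, by = c("condition", "species"),
                         suffix = c("_dep", "_rec"))
  j <- dplyr::filter(j, .data$level_dep > 0, .data$level_rec > 0)
  if (nrow(j) == 0) {
    abort("Need matched depletion-end and recovery-start observations.",
          class = "ergnet_config_error")
  }
  out <- j |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(k = -mean(log(.data$level_rec / .data$level_dep)) / t_chx,
                     .groups = "drop")
  setNames(out$k, out$species)[SPECIES]
}

# free-parameter map for one topology: what is optimized, on which scale
param_map <- function(topology, fit_k = FALSE,
                      K_range = c(0.05, 20), n_range = c(1, 4),
                      k_range = log(2) / c(24, 0.5)) {
  rows <- list()
  for (j in seq_along(LINKS)) {
    s <- topology[[j]]
    if (s == "0") next
    fr <- sign_fold_range(s)
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("f", j), slot = "f", j = j, scale = "log10",
      lower = log10(fr[1]), upper = log10(fr[2]))
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("K", j), slot = "K", j = j, scale = "log10",
      lower = log10(K_range[1]), upper = log10(K_range[2]))
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("n", j), slot = "n", j = j, scale = "linear",
      lower = n_range[1], upper = n_range[2])
  }
  if (fit_k) {
    rows[[length(rows) + 1]] <- data.frame(
      name = "k_e", slot = "k_e", j = NA, scale = "log10",
      lower = log10(k_range[1]), upper = log10(k_range[2]))
    rows[[length(rows) + 1]] <- data.frame(
      name = "k_g", slot = "k_g", j = NA, scale = "log10",
      lower = log10(k_range[1]), upper = log10(k_range[2]))
  }
  do.call(rbind, rows)
}

# assemble a packed theta from optimizer coordinates x (transformed scale)
map_to_theta <- function(x, map, base_theta) {
  th <- base_theta
  if (!is.null(map)) {
    vals <- ifelse(map$scale == "log10", 10^x, x)
    for (i in seq_len(nrow(map))) {
      slot <- map$slot[i]
      if (slot == "f") th[4 + map$j[i]] <- vals[i]
      else if (slot == "K") th[8 + map$j[i]] <- vals[i]
      else if (slot == "n") th[12 + map$j[i]] <- vals[i]
      else if (slot == "k_e") th[3] <- vals[i]
      else th[4] <- vals[i]
    }
  }
  # wild-type normalization: b_e, b_g are never free
  F1 <- hillF_r(1, th[5], th[9], th[13]); F2 <- hillF_r(1, th[6], th[10], th[14])
  F3 <- hillF_r(1, th[7], th[11], th[15]); F4 <- hillF_r(1, th[8], th[12], th[16])
  th[1] <- th[3] / (F1 * F2)
  th[2] <- th[4] / (F3 * F4)
  th
}

hillF_r <- function(x, f, K, n) {
  u <- (x / K)^n
  (1 + f * u) / (1 + u)
}

#' Fit one sign topology to perturbation time courses
#'
#' Multi-start bounded least squares: `n_starts` Latin-hypercube initial
#' points (seeded, reproducible) are each refined by Levenberg-Marquardt
#' with box bounds ([minpack.lm::nls.lm]). Free parameters are, for every
#' non-null link, the fold change `f_j` (log scale, bounded away from 1 by
#' its sign), the half-saturation `K_j` (log scale, 0.05-20) and the
#' cooperativity `n_j` (1-4); null links have `f_j` frozen at exactly 1.
#' Basal rates are always eliminated through the wild-type normalization.
#' Degradation rates are fixed — by default to the closed-form
#' cycloheximide-decay estimate ([estimate_degradation_rates()]), which
#' identifies them independently of regulation — or optionally fitted
#' (`fit_k = TRUE`).
#'
#' @inheritParams fit_error
#' @param topology The [topology()] to fit.
#' @param n_starts Number of Latin-hypercube starts.
#' @param seed Integer seed; identical seed and configuration give
#'   identical results.
#' @param k_fixed Named numeric `c(er = , gata3 = )` of degradation rates;
#'   `NULL` (default) estimates them from the data.
#' @param fit_k If `TRUE`, degradation rates are free parameters instead.
#' @return An object of class `ergnet_fit`: list with `topology`, `results`
#'   (tibble of all starts sorted by error, with packed parameter
#'   list-column), `data`, and the fit configuration. Use [best_params()],
#'   [generics::tidy()] and [generics::glance()].
#' @export
fit_topology <- function(data, topology, n_starts = 200, seed = 1,
                         k_fixed = NULL, fit_k = TRUE, sd_floor = 0.05,
                         sirna_efficiency = 0.9, t_sirna = 48, t_chx = 15) {
  topology <- as_topology(topology)
  design <- prepare_design(data, sd_floor, sirna_efficiency, t_sirna, t_chx)
  if (is.null(k_fixed) && !fit_k) {
    k_fixed <- estimate_degradation_rates(data, t_sirna, t_chx)
  }
  base <- model_params()
  base$f[] <- 1
  if (!fit_k) {
    base$k_e <- unname(k_fixed[["er"]])
    base$k_g <- unname(k_fixed[["gata3"]])
  }
  base_theta <- theta_vec(normalize_to_wt(base))
  map <- param_map(topology, fit_k = fit_k)
  objective <- function(x) design_residuals(map_to_theta(x, map, base_theta),
                                            design)

  set.seed(seed)
  npar <- if (is.null(map)) 0L else nrow(map)
  if (npar == 0L) {
    r <- objective(numeric(0))
    results <- tibble::tibble(start = 1L, error = sum(r^2), converged = TRUE,
                              theta = list(map_to_theta(numeric(0), map,
                                                        base_theta)))
  } else {
    starts <- lhs::randomLHS(n_starts, npar)
    lower <- map$lower; upper <- map$upper
    rows <- vector("list", n_starts)
    for (i in seq_len(n_starts)) {
      x0 <- lower + starts[i, ] * (upper - lower)
      fit <- tryCatch(
        suppressWarnings(
          minpack.lm::nls.lm(par = x0, lower = lower, upper = upper,
                           fn = objective,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 100, ptol = 1e-10, ftol = 1e-10))),
        error = function(e) NULL)
      if (is.null(fit)) {
        rows[[i]] <- tibble::tibble(start = i, error = Inf, converged = FALSE,
                                    theta = list(base_theta))
      } else {
        rows[[i]] <- tibble::tibble(
          start = i, error = sum(fit$fvec^2),
          converged = fit$info %in% 1:4,
          theta = list(map_to_theta(fit$par, map, base_theta)))
      }
    }
    results <- dplyr::bind_rows(rows)
  }
  results <- dplyr::arrange(dplyr::filter(results, is.finite(.data$error)),
                            .data$error)
  if (nrow(dplyr::filter(results, .data$converged)) == 0) {
    abort("No optimization start converged for this topology.",
          class = "ergnet_fitting_failure")
  }
  structure(list(topology = topology, results = results, data = data,
                 config = list(n_starts = n_starts, seed = seed,
                               k_fixed = k_fixed, fit_k = fit_k,
                               sd_floor = sd_floor,
                               sirna_efficiency = sirna_efficiency,
                               t_sirna = t_sirna, t_chx = t_chx)),
            class = "ergnet_fit")
}

#' Best-fitting parameter set of a fit
#'
#' @param fit An `ergnet_fit` object.
#' @param rank Which fit to extract (1 = lowest error).
#' @return An [model_params()] object.
#' @export
best_params <- function(fit, rank = 1) {
  theta_to_params(fit$results$theta[[rank]])
}

#' @export
print.ergnet_fit <- function(x, ...) {
  cat(sprintf("Topology fit [%s]: %d starts, best E = %.4g (seed %d)\n",
              format(x$topology), x$config$n_starts, x$results$error[1],
              x$config$seed))
  invisible(x)
}

#' Fit and rank a set of candidate topologies
#'
#' Fits each topology independently ([fit_topology()], seeds derived
#' deterministically as `seed + row - 1`) and assembles a leaderboard. A
#' topology is considered able to capture the data when its best error is
#' within `tolerance_factor` of the global best across candidates — the
#' configurable operationalization of errors "not significantly larger"
#' than the minimum.
#'
#' @inheritParams fit_topology
#' @param topologies A tibble from [enumerate_topologies()] or a list of
#'   [topology()] objects.
#' @param tolerance_factor Acceptance multiple of the global best error.
#' @param progress Print one line per fitted topology.
#' @return An object of class `ergnet_ranking`: list with `leaderboard`
#'   (tibble: link signs, `label`, `best_error`, `rel_error`, `pass`) and
#'   `fits` (list of `ergnet_fit`), ordered as supplied.
#' @export
rank_topologies <- function(data, topologies = enumerate_topologies(
                              free_links = c("er_auto", "gata3_auto"),
                              fixed_signs = c(gata3_to_er = "+",
                                              er_to_gata3 = "-")),
                            n_starts = 200, seed = 1, tolerance_factor = 2,
                            k_fixed = NULL, fit_k = TRUE, sd_floor = 0.05,
                            sirna_efficiency = 0.9, t_sirna = 48, t_chx = 15,
                            progress = FALSE) {
  topo_list <- if (is.data.frame(topologies)) topologies$topology else topologies
  if (is.null(k_fixed) && !fit_k) {
    k_fixed <- estimate_degradation_rates(data, t_sirna, t_chx)
  }
  fits <- vector("list", length(topo_list))
  for (i in seq_along(topo_list)) {
    fits[[i]] <- fit_topology(data, topo_list[[i]], n_starts = n_starts,
                              seed = seed + i - 1L, k_fixed = k_fixed,
                              fit_k = fit_k, sd_floor = sd_floor,
                              sirna_efficiency = sirna_efficiency,
                              t_sirna = t_sirna, t_chx = t_chx)
    if (progress) {
      cat(sprintf("  fitted %s: best E = %.4g\n",
                  format(topo_list[[i]]), fits[[i]]$results$error[1]))
    }
  }
  best <- vapply(fits, function(f) f$results$error[1], numeric(1))
  lb <- purrr::map_dfr(topo_list, function(tp) {
    tibble::as_tibble(as.list(setNames(unclass(tp), LINKS)))
  })
  lb$label <- vapply(topo_list, format, character(1))
  lb$best_error <- best
  lb$rel_error <- best / min(best)
  lb$pass <- lb$rel_error <= tolerance_factor
  structure(list(leaderboard = lb, fits = fits,
                 tolerance_factor = tolerance_factor, seed = seed),
            class = "ergnet_ranking")
}

#' @export
print.ergnet_ranking <- function(x, ...) {
  cat(sprintf("Topology ranking (%d candidates, tolerance %.3gx best):\n",
              nrow(x$leaderboard), x$tolerance_factor))
  print(dplyr::arrange(
    dplyr::select(x$leaderboard, -dplyr::any_of("topology")),
    .data$best_error), n = Inf)
  invisible(x)
}
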