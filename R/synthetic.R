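#' Calibrated ground-truth network for synthetic experiments
#'
#' The default data-generating model: the inferred network sign structure
#' (GATA3 activates ERalpha, ERalpha weakly represses GATA3, positive GATA3
#' autoregulation, no ERalpha autoregulation) with fold changes calibrated
#' once so that, at siRNA efficiency 0.9, the knockdown steady states
#' reproduce the measured population shifts: ERalpha drops to ~50% of wild
#' type under GATA3 knockdown and GATA3 rises to ~115% under ERalpha
#' knockdown (both read at the 48 h endpoint of the depletion protocol).
#' Degradation rates encode a slowly turned-over ERalpha (half-life ~17 h)
#' and a rapidly degraded GATA3 (half-life ~1 h); half-saturation constants
#' place the wild-type operating point below saturation so that regulatory
#' links carry appreciable local gain and the negative feedback loop
#' measurably suppresses expression noise. These values are calibration
#' choices of the package, not measured constants.
#'
#' @param er_auto Sign of ERalpha autoregulation for variant ground truths
#'   (`"0"` default; `"+"` or `"-"` adjust `f1` to 3 or 1/3 with `K1 = 1`,
#'   `n1 = 2`).
#' @return A list with elements `topology` ([topology()]) and `params`
#'   ([model_params()], wild-type normalized).
#' @export
default_ground_truth <- function(er_auto = "0") {
  er_auto <- normalize_sign(er_auto)
  f1 <- switch(er_auto, "0" = 1, "+" = 3, "-" = 1 / 3)
  topo <- topology(er_auto = er_auto)
  # f2, f3 solved from the two knockdown endpoint conditions (see vignette)
  params <- model_params(
    k_e = 0.04, k_g = 0.7,
    f = c(f1, 40.9926461, 0.1243758, 6),
    K = c(1, 3, 1.6, 0.4),
    n = c(2, 3, 4, 3)
  )
  params <- normalize_to_wt(params, topo)
  list(topology = topo, params = params)
}

#' Configuration of the synthetic-data generator
#'
#' Bundles the ground-truth model, the perturbation schedule of the emulated
#' experiments and the measurement-noise model. The defaults reproduce the
#' study conditions: 48 h siRNA depletion sampled every 12 h, a 15 h
#' cycloheximide block followed by a 10 h recovery sampled at
#' 0, 1, 2, 4, 6, 8, 10 h post-washout, multiplicative lognormal
#' measurement noise with CV 0.1 (western-blot densitometry is ratio-scale)
#' and 3 replicates.
#'
#' @param ground_truth List with `topology` and `params`, as returned by
#'   [default_ground_truth()].
#' @param sirna_efficiency Knockdown efficiency in `[0, 1)`.
#' @param noise_cv Measurement coefficient of variation in `[0, 0.5]`.
#' @param noise_model `"lognormal"` (mean-preserving multiplicative, default)
#'   or `"gaussian"` (additive, sd = `noise_cv` x level).
#' @param n_replicates Replicates per observation (>= 1).
#' @param depletion_times Sampling times of the depletion phase, hours.
#' @param recovery_times Sampling times after cycloheximide washout, hours.
#' @param t_sirna Duration of siRNA incubation before the block, hours.
#' @param t_chx Duration of the cycloheximide window, hours.
#' @param seed Integer seed; generation is seed-reproducible.
#' @return A list of class `ergnet_generator_config`.
#' @export
generator_config <- function(ground_truth = default_ground_truth(),
                             sirna_efficiency = 0.9, noise_cv = 0.1,
                             noise_model = c("lognormal", "gaussian"),
                             n_replicates = 3,
                             depletion_times = c(0, 12, 24, 36, 48),
                             recovery_times = c(0, 1, 2, 4, 6, 8, 10),
                             t_sirna = 48, t_chx = 15, seed = 1) {
  noise_model <- match.arg(noise_model)
  if (noise_cv < 0 || noise_cv > 0.5) {
    abort("`noise_cv` must lie in [0, 0.5].", class = "ergnet_config_error")
  }
  if (n_replicates < 1) {
    abort("`n_replicates` must be >= 1.", class = "ergnet_config_error")
  }
  validate_params(ground_truth$params, ground_truth$topology)
  structure(list(ground_truth = ground_truth,
                 sirna_efficiency = sirna_efficiency, noise_cv = noise_cv,
                 noise_model = noise_model, n_replicates = n_replicates,
                 depletion_times = depletion_times,
                 recovery_times = recovery_times, t_sirna = t_sirna,
                 t_chx = t_chx, seed = as.integer(seed)),
            class = "ergnet_generator_config")
}

gen_conditions <- function(config) {
  list(control = perturbation("none", config$sirna_efficiency),
       si_er = perturbation("er", config$sirna_efficiency),
       si_gata3 = perturbation("gata3", config$sirna_efficiency))
}

apply_noise <- function(levels, config) {
  cv <- config$noise_cv
  if (cv == 0) return(levels)
  if (config$noise_model == "lognormal") {
    s <- sqrt(log1p(cv^2))
    levels * rlnorm(length(levels), meanlog = -s^2 / 2, sdlog = s)
  } else {
    pmax(levels + rnorm(length(levels), sd = cv * levels), 0)
  }
}

noisy_observations <- function(true_tbl, config) {
  reps <- purrr::map_dfr(seq_len(config$n_replicates), function(r) {
    out <- true_tbl
    out$level <- apply_noise(true_tbl$level, config)
    out$replicate <- r
    out
  })
  reps |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("condition", "phase", "time_h", "species")))) |>
    dplyr::summarise(
      sd = if (dplyr::n() > 1) sd(.data$level) else 0,
      level = mean(.data$level),
      n_rep = dplyr::n(), .groups = "drop") |>
    dplyr::select(dplyr::all_of(
      c("condition", "phase", "time_h", "species", "level", "sd", "n_rep")))
}

#' Generate synthetic siRNA depletion time courses
#'
#' Simulates the ground-truth model from the wild-type state `(1, 1)` under
#' control, ERalpha and GATA3 siRNA, samples both proteins at the configured
#' times, applies measurement noise per replicate and reports the per-time
#' replicate mean and standard deviation — emulating western-blot
#' quantification of a depletion experiment.
#'
#' @param config [generator_config()].
#' @return A tidy tibble with columns `condition`, `phase` (`"depletion"`),
#'   `time_h`, `species`, `level`, `sd`, `n_rep`.
#' @export
generate_depletion_timecourses <- function(config) {
  set.seed(config$seed)
  theta <- theta_vec(config$ground_truth$params)
  conds <- gen_conditions(config)
  true_tbl <- purrr::imap_dfr(conds, function(cond, label) {
    m <- sim_matrix(theta, cond, config$depletion_times)
    tibble::tibble(condition = label, phase = "depletion",
                   time_h = rep(config$depletion_times, 2),
                   species = rep(SPECIES, each = length(config$depletion_times)),
                   level = c(m[, 1], m[, 2]))
  })
  noisy_observations(true_tbl, config)
}

#' Generate synthetic cycloheximide-recovery time courses
#'
#' Emulates the double-perturbation protocol that isolates autoregulation:
#' for each siRNA condition (including control) the model is run for
#' `t_sirna` hours of knockdown, then `t_chx` hours with both synthesis
#' rates zero (cycloheximide, siRNA continued), and the recovery after
#' washout (siRNA still continued) is sampled at the configured post-washout
#' times.
#'
#' @param config [generator_config()].
#' @return A tidy tibble as in [generate_depletion_timecourses()], with
#'   `phase = "recovery"` and `time_h` measured from washout.
#' @export
generate_recovery_timecourses <- function(config) {
  set.seed(config$seed + 1L)
  theta <- theta_vec(config$ground_truth$params)
  conds <- gen_conditions(config)
  true_tbl <- purrr::imap_dfr(conds, function(cond, label) {
    m <- sim_recovery_matrix(theta, cond, config$recovery_times,
                             config$t_sirna, config$t_chx)
    tibble::tibble(condition = label, phase = "recovery",
                   time_h = rep(config$recovery_times, 2),
                   species = rep(SPECIES, each = length(config$recovery_times)),
                   level = c(m[, 1], m[, 2]))
  })
  noisy_observations(true_tbl, config)
}

# depletion -> CHX -> recovery, observed at times (hours post washout)
sim_recovery_matrix <- function(theta, cond, times_post, t_sirna = 48,
                                t_chx = 15, rtol = 1e-8) {
  sc <- cond_scalars(cond)
  dep <- ode_segment_cpp(theta, sc$se, sc$sg, sc$ici_act, sc$k_loss,
                         c(1, 1), 0, t_sirna, rtol, 1e-10)
  chx <- ode_segment_cpp(theta, 0, 0, sc$ici_act, sc$k_loss,
                         dep[1, ], 0, t_chx, rtol, 1e-10)
  ode_segment_cpp(theta, sc$se, sc$sg, sc$ici_act, sc$k_loss,
                  chx[1, ], 0, times_post, rtol, 1e-10)
}

#' Generate a synthetic ICI dose-response table
#'
#' Steady-state ERalpha mRNA proxy (see [mrna_proxy()]) of the ground-truth
#' model across an ICI dose ladder, normalized to dose 0, with multiplicative
#' measurement noise across replicates — emulating a qPCR dose-response
#' experiment read out at steady state.
#'
#' @param config [generator_config()].
#' @param doses Dose ladder in nM; must include 0 (first entry after sorting).
#' @param ici_k50,k_ici ICI mechanism parameters, see [perturbation()].
#' @return A tibble with columns `dose_nM`, `level` (replicate mean of the
#'   normalized proxy), `sd`, `n_rep`.
#' @export
generate_dose_response <- function(config, doses = c(0, 0.1, 1, 10, 100),
                                   ici_k50 = 3, k_ici = 1) {
  if (!any(doses == 0)) {
    abort("`doses` must include 0 (the normalization point).",
          class = "ergnet_config_error")
  }
  set.seed(config$seed + 2L)
  doses <- sort(doses)
  p <- config$ground_truth$params
  proxy <- vapply(doses, function(d) {
    cond <- perturbation(ici_dose = d, ici_k50 = ici_k50, k_ici = k_ici)
    y <- steady_state_from(p, cond, seed_state = c(1, 1))
    if (is.null(y)) {
      st <- stable_state(p, cond)$stable
      if (nrow(st) == 0) abort("No stable steady state at a dose.",
                               class = "ergnet_search_failure")
      y <- c(st$e[1], st$g[1])
    }
    mrna_proxy(c(e = y[1], g = y[2]), p, cond)
  }, numeric(1))
  proxy <- proxy / proxy[doses == 0]
  reps <- purrr::map_dfr(seq_len(config$n_replicates), function(r) {
    tibble::tibble(dose_nM = doses, level = apply_noise(proxy, config),
                   replicate = r)
  })
  reps |>
    dplyr::group_by(.data$dose_nM) |>
    dplyr::summarise(sd = if (dplyr::n() > 1) sd(.data$level) else 0,
                     level = mean(.data$level),
                     n_rep = dplyr::n(), .groups = "drop") |>
    dplyr::select(dplyr::all_of(c("dose_nM", "level", "sd", "n_rep")))
}

#' Generate the full synthetic perturbation dataset
#'
#' Convenience wrapper binding [generate_depletion_timecourses()] and
#' [generate_recovery_timecourses()] into the single tidy table consumed by
#' [fit_topology()] and [rank_topologies()].
#'
#' @param config [generator_config()].
#' @return A tidy tibble of depletion and recovery observations.
#' @export
generate_timecourses <- function(config) {
  dplyr::bind_rows(generate_depletion_timecourses(config),
                   generate_recovery_timecourses(config))
}
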