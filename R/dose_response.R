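#' Classify the direction of a dose-response curve
#'
#' Labels a sequence of normalized responses as `"increasing"`,
#' `"decreasing"`, `"flat"` or `"non-monotone"` from its successive
#' differences; differences within `±tol` do not count as direction changes.
#'
#' @param values Numeric responses, ordered by dose.
#' @param tol Tolerance on successive differences.
#' @return A single label string.
#' @export
classify_monotonic <- function(values, tol = 1e-4) {
  d <- diff(values)
  up <- any(d > tol)
  down <- any(d < -tol)
  if (up && down) return("non-monotone")
  if (up) return("increasing")
  if (down) return("decreasing")
  "flat"
}

#' Steady-state ICI dose-response of the ERalpha mRNA proxy
#'
#' For each dose of the ERalpha antagonist ICI 182,780, solves the perturbed
#' steady state of the model and reports the ERalpha mRNA proxy
#' ([mrna_proxy()]) normalized to dose 0, together with a monotonicity
#' label. The shape of this curve discriminates ERalpha-autoregulation
#' topologies: positive autoregulation predicts a monotonically decreasing
#' curve, absent autoregulation a monotonically increasing one.
#'
#' If the system is multistable at some dose the curve is labeled
#' `"ambiguous"` and all stable branches are reported.
#'
#' @param object An `ergnet_fit` (its best-fit parameters are used), or an
#'   [model_params()] object.
#' @param doses Sorted dose ladder in nM; the first dose must be 0.
#' @param ici_k50,k_ici ICI mechanism parameters, see [perturbation()].
#' @param tol Monotonicity tolerance on successive normalized differences.
#' @param n_best If `object` is a fit, compute one curve per each of the
#'   `n_best` best parameter sets (default 1: best fit only).
#' @return A tibble with columns `rank`, `dose_nM`, `branch`, `proxy`,
#'   `label`. For single-branch curves `branch` is 1 throughout.
#' @export
ici_dose_response <- function(object, doses = c(0, 0.1, 1, 10, 100),
                              ici_k50 = 3, k_ici = 1, tol = 1e-4,
                              n_best = 1) {
  if (is.unsorted(doses) || doses[1] != 0) {
    abort("`doses` must be sorted with the first dose equal to 0.",
          class = "ergnet_config_error")
  }
  param_sets <- if (inherits(object, "ergnet_fit")) {
    n_best <- min(n_best, nrow(object$results))
    lapply(seq_len(n_best), function(i) best_params(object, i))
  } else {
    list(object)
  }
  purrr::imap_dfr(param_sets, function(p, rank) {
    rows <- purrr::map_dfr(doses, function(d) {
      cond <- perturbation(ici_dose = d, ici_k50 = ici_k50, k_ici = k_ici)
      st <- stable_state(p, cond)$stable
      if (nrow(st) == 0) {
        abort("No stable steady state at a dose.",
              class = "ergnet_search_failure")
      }
      purrr::map_dfr(seq_len(nrow(st)), function(b) {
        tibble::tibble(dose_nM = d, branch = b,
                       proxy = mrna_proxy(c(e = st$e[b], g = st$g[b]), p, cond))
      })
    })
    multi <- any(duplicated(rows$dose_nM))
    base <- rows$proxy[rows$dose_nM == 0][1]
    rows$proxy <- rows$proxy / base
    lab <- if (multi) "ambiguous" else classify_monotonic(rows$proxy, tol)
    tibble::tibble(rank = rank, rows, label = lab)
  })
}
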