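#' Logarithmic-gain ensemble of a fitted link
#'
#' Evaluates the logarithmic gain ([log_gain()]) of one regulatory link at
#' the wild-type operating point (`x = 1` in normalized units) across the
#' `n_best` best-fit parameter sets of a fit — the ensemble used to compare
#' regulatory-link strengths between candidate topologies.
#'
#' @param fit An `ergnet_fit` from [fit_topology()].
#' @param link Link name (`"er_auto"`, `"gata3_to_er"`, `"er_to_gata3"`,
#'   `"gata3_auto"`).
#' @param n_best Ensemble size (default 50 best-fit parameter sets).
#' @param x Evaluation level.
#' @return A tibble with columns `rank`, `error`, `gain`.
#' @export
gain_ensemble <- function(fit, link = "er_auto", n_best = 50, x = 1) {
  j <- match.arg(link, LINKS)
  j <- match(j, LINKS)
  n_best <- min(n_best, nrow(fit$results))
  purrr::map_dfr(seq_len(n_best), function(i) {
    p <- theta_to_params(fit$results$theta[[i]])
    tibble::tibble(rank = i, error = fit$results$error[i],
                   gain = unname(log_gain(x, p$f[j], p$K[j], p$n[j])))
  })
}

#' Eliminate a regulatory link from a parameter set
#'
#' Sets the link's fold change to exactly 1 (no regulation), leaves every
#' other parameter unchanged and re-applies the wild-type normalization so
#' the unperturbed steady state remains `(1, 1)`.
#'
#' @param params [model_params()].
#' @param link Link name.
#' @return The modified `ergnet_params`.
#' @export
eliminate_link <- function(params, link = "er_auto") {
  j <- match(match.arg(link, LINKS), LINKS)
  params$f[j] <- 1
  normalize_to_wt(params)
}

#' Error change after eliminating a link, across best fits
#'
#' For each of the `n_best` best-fit parameter sets, sets the chosen link's
#' fold change to 1 (re-normalizing the basal rates), recomputes the fit
#' error on the same datasets and reports the percentage change
#' `100 (E_eliminated - E_fit) / E_fit`. A fitted link whose influence is
#' negligible yields changes near zero; eliminating a genuinely load-bearing
#' link inflates the error by orders of magnitude more.
#'
#' @param fit An `ergnet_fit`.
#' @param link Link to eliminate.
#' @param data Observation table; defaults to the data the fit was run on.
#' @param n_best Number of best-fit parameter sets to process.
#' @return A tibble with columns `rank`, `error`, `error_eliminated`,
#'   `pct_change` (and `abs_change` as a fallback measure when
#'   `error == 0`, where the percentage is undefined and returned `NA`).
#' @export
link_elimination_error_change <- function(fit, link = "er_auto", data = NULL,
                                          n_best = 50) {
  data <- data %||% fit$data
  cfg <- fit$config
  design <- prepare_design(data, cfg$sd_floor, cfg$sirna_efficiency,
                           cfg$t_sirna, cfg$t_chx)
  n_best <- min(n_best, nrow(fit$results))
  purrr::map_dfr(seq_len(n_best), function(i) {
    p <- theta_to_params(fit$results$theta[[i]])
    E0 <- sum(design_residuals(theta_vec(p), design)^2)
    p1 <- eliminate_link(p, link)
    E1 <- sum(design_residuals(theta_vec(p1), design)^2)
    tibble::tibble(rank = i, error = E0, error_eliminated = E1,
                   pct_change = ifelse(E0 > 0, 100 * (E1 - E0) / E0, NA_real_),
                   abs_change = E1 - E0)
  })
}
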