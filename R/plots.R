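#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

species_labels <- c(er = "ERα", gata3 = "GATA3")

#' Plot a fitted topology against the data
#'
#' Observed normalized levels (points, with error bars where replicate
#' standard deviations are available) overlaid with the best-fit model
#' trajectories, faceted by phase and condition.
#'
#' @param object An `ergnet_fit`.
#' @param rank Which ranked parameter set to draw (1 = best).
#' @param n_curve Number of time points per simulated curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ergnet_fit <- function(object, rank = 1, n_curve = 80, ...) {
  data <- object$data
  cfg <- object$config
  theta <- object$results$theta[[rank]]
  curves <- purrr::map_dfr(
    dplyr::group_split(dplyr::group_by(data, .data$condition, .data$phase)),
    function(d) {
      target <- switch(d$condition[1], control = "none", si_er = "er",
                       si_gata3 = "gata3")
      cond <- perturbation(target, cfg$sirna_efficiency)
      tt <- seq(min(d$time_h), max(d$time_h), length.out = n_curve)
      m <- if (d$phase[1] == "depletion") {
        sim_matrix(theta, cond, tt)
      } else {
        sim_recovery_matrix(theta, cond, tt, cfg$t_sirna, cfg$t_chx)
      }
      tibble::tibble(condition = d$condition[1], phase = d$phase[1],
                     time_h = rep(tt, 2),
                     species = rep(SPECIES, each = length(tt)),
                     level = c(m[, 1], m[, 2]))
    })
  ggplot2::ggplot(data, ggplot2::aes(.data$time_h, .data$level,
                                     colour = .data$species)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$level - .data$sd,
                                        ymax = .data$level + .data$sd),
                           width = 0, alpha = 0.5) +
    ggplot2::geom_line(data = curves) +
    ggplot2::facet_grid(phase ~ condition, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(er = "#B2182B", gata3 = "#2166AC"),
                                 labels = species_labels, name = NULL) +
    ggplot2::labs(x = "time (h)", y = "normalized level",
                  title = sprintf("Topology %s, E = %.3g",
                                  format(object$topology),
                                  object$results$error[rank])) +
    ggplot2::theme_bw()
}

#' Plot a topology leaderboard
#'
#' @param object An `ergnet_ranking`.
#' @param ... Unused.
#' @return A ggplot object: best error per candidate topology, the
#'   acceptance threshold drawn as a dashed line.
#' @export
autoplot.ergnet_ranking <- function(object, ...) {
  lb <- dplyr::arrange(object$leaderboard, .data$best_error)
  lb$label <- factor(lb$label, levels = lb$label)
  ggplot2::ggplot(lb, ggplot2::aes(.data$label, .data$best_error,
                                   fill = .data$pass)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = min(lb$best_error) *
                          object$tolerance_factor, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166AC",
                                          `FALSE` = "grey65"),
                               name = "captures data") +
    ggplot2::labs(x = "topology (signs of links 1-4)", y = "best fit error E") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot ICI dose-response curves
#'
#' @param curves Output of [ici_dose_response()] (possibly several ranks).
#' @return A ggplot object on a log-ish dose axis (zero dose drawn at the
#'   smallest positive dose / 10).
#' @export
plot_dose_response <- function(curves) {
  eps <- min(curves$dose_nM[curves$dose_nM > 0]) / 10
  curves$dose_plot <- ifelse(curves$dose_nM == 0, eps, curves$dose_nM)
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$dose_plot, .data$proxy,
                               group = interaction(.data$rank, .data$branch),
                               colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ICI dose (nM, 0 plotted at left edge)",
                  y = "steady-state ERα mRNA proxy (dose 0 = 1)",
                  colour = "direction") +
    ggplot2::theme_bw()
}

#' Plot noise summaries
#'
#' @param summaries A named list of `ergnet_noise` objects (names used as
#'   group labels, e.g. `list(WT = ..., "no GATA3→ER" = ...)`).
#' @return A ggplot bar chart of CV per species and group.
#' @export
plot_noise <- function(summaries) {
  df <- purrr::imap_dfr(summaries, function(s, nm) {
    dplyr::mutate(tidy(s), group = nm)
  })
  df$group <- factor(df$group, levels = names(summaries))
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$cv,
                                   fill = .data$species)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(er = "#B2182B", gata3 = "#2166AC"),
                               labels = species_labels, name = NULL) +
    ggplot2::labs(x = NULL, y = "CV = σ/μ") +
    ggplot2::theme_bw()
}
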