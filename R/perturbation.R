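#' Experimental perturbation conditions
#'
#' Describes how an in-silico experiment perturbs the network:
#'
#' * **siRNA knockdown** of one factor, modeled as a constant multiplicative
#'   scaling `1 - efficiency` of the targeted gene's synthesis rate for the
#'   duration of the condition.
#' * **Cycloheximide (CHX)**, a translation inhibitor, modeled as both
#'   synthesis rates set exactly to zero inside the window
#'   `[t_on, t_off]` (hours); degradation continues.
#' * **ICI 182,780 (fulvestrant)**, which sequesters ERalpha and induces its
#'   depletion independently of transcription. Modeled with two interpretable
#'   parameters: the regulatorily *active* ERalpha entering all Hill terms is
#'   `e_active = e / (1 + dose/ici_k50)` (sequestration), and total ERalpha
#'   acquires an additional first-order loss `k_ici * (dose/ici_k50) * e`
#'   (induced degradation).
#'
#' @param sirna_target `"none"`, `"er"` or `"gata3"` (at most one target).
#' @param sirna_efficiency Fraction in `[0, 1)` by which the target's
#'   synthesis rate is reduced. Default 0.9 (efficient knockdown).
#' @param chx_window Optional numeric `c(t_on, t_off)` in hours with
#'   `t_on < t_off`, or `NULL`.
#' @param ici_dose ICI concentration in nM (>= 0).
#' @param ici_k50 Dose at which ERalpha inactivation is half-maximal, nM.
#' @param k_ici Scale of the ICI-induced ERalpha loss rate, per hour.
#' @return An object of class `ergnet_perturbation`.
#' @examples
#' perturbation()                                  # unperturbed
#' perturbation("gata3", 0.9)                      # GATA3 knockdown
#' perturbation("er", 0.9, chx_window = c(48, 63)) # knockdown + CHX chase
#' @export
perturbation <- function(sirna_target = "none", sirna_efficiency = 0.9,
                         chx_window = NULL, ici_dose = 0, ici_k50 = 3,
                         k_ici = 1) {
  if (!is.character(sirna_target) || length(sirna_target) != 1 ||
      !sirna_target %in% c("none", "er", "gata3")) {
    abort("`sirna_target` must be one of 'none', 'er', 'gata3'.",
          class = "ergnet_config_error")
  }
  if (!is.numeric(sirna_efficiency) || sirna_efficiency < 0 ||
      sirna_efficiency >= 1) {
    abort("`sirna_efficiency` must lie in [0, 1).", class = "ergnet_config_error")
  }
  if (!is.null(chx_window)) {
    if (length(chx_window) != 2 || chx_window[1] >= chx_window[2]) {
      abort("`chx_window` must be c(t_on, t_off) with t_on < t_off.",
            class = "ergnet_config_error")
    }
  }
  if (ici_dose < 0 || ici_k50 <= 0 || k_ici < 0) {
    abort("ICI parameters require dose >= 0, k50 > 0, k_ici >= 0.",
          class = "ergnet_config_error")
  }
  structure(list(sirna_target = sirna_target,
                 sirna_efficiency = sirna_efficiency,
                 chx_window = chx_window, ici_dose = ici_dose,
                 ici_k50 = ici_k50, k_ici = k_ici),
            class = "ergnet_perturbation")
}

#' @export
print.ergnet_perturbation <- function(x, ...) {
  cat("Perturbation condition:\n")
  if (x$sirna_target == "none") cat("  siRNA: none\n")
  else cat(sprintf("  siRNA: %s (efficiency %.2f)\n", x$sirna_target,
                   x$sirna_efficiency))
  if (!is.null(x$chx_window)) {
    cat(sprintf("  cycloheximide window: [%g, %g] h\n", x$chx_window[1],
                x$chx_window[2]))
  }
  if (x$ici_dose > 0) {
    cat(sprintf("  ICI: %g nM (K50 %g nM, k_ici %g /h)\n", x$ici_dose,
                x$ici_k50, x$k_ici))
  }
  invisible(x)
}

# constant-in-time perturbation scalars; CHX handled by segmentation
cond_scalars <- function(cond, in_chx = FALSE) {
  se <- if (cond$sirna_target == "er") 1 - cond$sirna_efficiency else 1
  sg <- if (cond$sirna_target == "gata3") 1 - cond$sirna_efficiency else 1
  if (in_chx) se <- sg <- 0
  r <- cond$ici_dose / cond$ici_k50
  list(se = se, sg = sg, ici_act = 1 / (1 + r), k_loss = cond$k_ici * r)
}
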