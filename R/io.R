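#' Read and write tidy time-course tables
#'
#' The on-disk dialect is a plain CSV with columns `condition`, `phase`,
#' `time_h`, `species`, `level`, `sd` (and optionally `n_rep`), matching the
#' tables produced by the synthetic-data generator and consumed by the
#' fitting functions.
#'
#' @param data A tidy observation tibble.
#' @param path File path.
#' @return `read_timecourses()` returns the validated tibble;
#'   `write_timecourses()` returns `path` invisibly.
#' @export
write_timecourses <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_timecourses
#' @export
read_timecourses <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("condition", "phase", "time_h", "species", "level", "sd")
  if (!all(req %in% names(data))) {
    abort(paste("Time-course file must contain columns:",
                paste(req, collapse = ", ")), class = "ergnet_config_error")
  }
  if (any(data$level <= 0) || any(data$sd < 0) || any(data$time_h < 0)) {
    abort("Levels must be positive, sd and times non-negative.",
          class = "ergnet_config_error")
  }
  data
}

#' Read a model/condition configuration from YAML
#'
#' Accepts a YAML file with optional blocks `topology` (link signs),
#' `params` (`b_e`, `b_g`, `k_e`, `k_g`, `f`, `K`, `n`), and `generator`
#' (fields of [generator_config()] other than the ground truth).
#'
#' @param path YAML file path.
#' @return A list with elements `topology`, `params`, `generator_args`.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  topo <- if (!is.null(y$topology)) do.call(topology, as.list(y$topology))
          else topology()
  params <- if (!is.null(y$params)) do.call(model_params, y$params)
            else default_ground_truth()$params
  list(topology = topo, params = params,
       generator_args = y$generator %||% list())
}

#' Write a fit result to JSON
#'
#' Serializes topology signs, the best-fit parameter values, error, seed and
#' start count — enough to reproduce and audit the fit.
#'
#' @param fit An `ergnet_fit`.
#' @param path Output JSON path.
#' @param n_best How many ranked parameter sets to include.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, n_best = 1) {
  n_best <- min(n_best, nrow(fit$results))
  sets <- lapply(seq_len(n_best), function(i) {
    p <- best_params(fit, i)
    list(error = fit$results$error[i],
         params = list(b_e = p$b_e, b_g = p$b_g, k_e = p$k_e, k_g = p$k_g,
                       f = unname(p$f), K = unname(p$K), n = unname(p$n)))
  })
  jsonlite::write_json(
    list(topology = as.list(setNames(unclass(fit$topology), LINKS)),
         seed = fit$config$seed, n_starts = fit$config$n_starts,
         best_fits = sets),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
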