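#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a topology fit
#'
#' One row per optimization start (sorted by error), with the fitted
#' parameter values unpacked into columns.
#'
#' @param x An `ergnet_fit`.
#' @param ... Unused.
#' @return A tibble with columns `rank`, `start`, `error`, `converged`,
#'   `b_e`, `b_g`, `k_e`, `k_g`, `f1`-`f4`, `K1`-`K4`, `n1`-`n4`.
#' @export
tidy.ergnet_fit <- function(x, ...) {
  purrr::imap_dfr(x$results$theta, function(th, i) {
    tibble::tibble(rank = i, start = x$results$start[i],
                   error = x$results$error[i],
                   converged = x$results$converged[i],
                   b_e = th[1], b_g = th[2], k_e = th[3], k_g = th[4],
                   !!!setNames(as.list(th[5:8]), paste0("f", 1:4)),
                   !!!setNames(as.list(th[9:12]), paste0("K", 1:4)),
                   !!!setNames(as.list(th[13:16]), paste0("n", 1:4)))
  })
}

#' Glance at a topology fit
#'
#' @param x An `ergnet_fit`.
#' @param ... Unused.
#' @return A one-row tibble: topology label, best error, number of
#'   converged starts, total starts and seed.
#' @export
glance.ergnet_fit <- function(x, ...) {
  tibble::tibble(topology = format(x$topology),
                 best_error = x$results$error[1],
                 n_converged = sum(x$results$converged),
                 n_starts = x$config$n_starts, seed = x$config$seed)
}

#' Tidy a topology ranking
#'
#' @param x An `ergnet_ranking`.
#' @param ... Unused.
#' @return The leaderboard tibble (one row per candidate topology).
#' @export
tidy.ergnet_ranking <- function(x, ...) x$leaderboard

#' Tidy a noise summary
#'
#' @param x An `ergnet_noise`.
#' @param ... Unused.
#' @return A tibble with one row per species: `species`, `mean`, `cv`.
#' @export
tidy.ergnet_noise <- function(x, ...) {
  tibble::tibble(species = SPECIES, mean = c(x$mean_e, x$mean_g),
                 cv = c(x$cv_e, x$cv_g), method = x$method)
}

#' Tidy a sign topology
#'
#' @param x An `ergnet_topology`.
#' @param ... Unused.
#' @return A tibble with columns `link`, `j`, `sign`.
#' @export
tidy.ergnet_topology <- function(x, ...) {
  tibble::tibble(link = LINKS, j = seq_along(LINKS), sign = unname(unclass(x)[LINKS]))
}
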