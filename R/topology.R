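#' Sign topology of the ERalpha-GATA3 network
#'
#' A regulatory topology assigns one of three signs to each of the four
#' potential links of the two-gene network: ERalpha autoregulation
#' (`er_auto`, link 1), GATA3 regulation of ERalpha (`gata3_to_er`, link 2),
#' ERalpha regulation of GATA3 (`er_to_gata3`, link 3) and GATA3
#' autoregulation (`gata3_auto`, link 4). Signs are `"+"` (activation,
#' fold change f > 1), `"-"` (repression, 0 < f < 1) or `"0"` (absent link,
#' f = 1); the long names `"positive"`, `"negative"` and `"null"` are also
#' accepted.
#'
#' The default topology is the inferred final network: an overall negative
#' feedback loop between the two factors (GATA3 activates ERalpha, ERalpha
#' represses GATA3), positive GATA3 autoregulation and no ERalpha
#' autoregulation.
#'
#' @param er_auto,gata3_to_er,er_to_gata3,gata3_auto Link signs.
#' @return An object of class `ergnet_topology`: a named character vector of
#'   four signs.
#' @examples
#' topology()                       # the inferred network
#' topology(er_auto = "+")          # variant with positive ERalpha autoregulation
#' @export
topology <- function(er_auto = "0", gata3_to_er = "+", er_to_gata3 = "-",
                     gata3_auto = "+") {
  signs <- vapply(list(er_auto, gata3_to_er, er_to_gata3, gata3_auto),
                  normalize_sign, character(1))
  structure(setNames(signs, LINKS), class = "ergnet_topology")
}

normalize_sign <- function(s) {
  s <- as.character(s)
  out <- switch(s,
    "+" = "+", "positive" = "+", "pos" = "+",
    "-" = "-", "negative" = "-", "neg" = "-",
    "0" = "0", "null" = "0", "none" = "0", "absent" = "0",
    abort(paste0("Unknown link sign: '", s, "'. Use '+', '-' or '0'."),
          class = "ergnet_config_error")
  )
  out
}

#' @export
print.ergnet_topology <- function(x, ...) {
  cat("ERalpha-GATA3 sign topology\n")
  lab <- c(er_auto = "ERalpha autoregulation   (F1)",
           gata3_to_er = "GATA3 -> ERalpha         (F2)",
           er_to_gata3 = "ERalpha -> GATA3         (F3)",
           gata3_auto = "GATA3 autoregulation     (F4)")
  for (l in LINKS) cat(sprintf("  %s : %s\n", lab[[l]], x[[l]]))
  invisible(x)
}

#' @export
format.ergnet_topology <- function(x, ...) paste(unclass(x), collapse = "")

as_topology <- function(x) {
  if (inherits(x, "ergnet_topology")) return(x)
  if (is.character(x) && length(x) == 4) {
    return(topology(x[[1]], x[[2]], x[[3]], x[[4]]))
  }
  abort("Cannot interpret input as a sign topology.",
        class = "ergnet_config_error")
}

#' Enumerate sign topologies
#'
#' Generates every assignment of signs `{+, -, 0}` to a chosen subset of the
#' four regulatory links, holding the remaining links at fixed signs. With
#' all four links free this yields the 3^4 = 81 possible regulatory
#' scenarios; with only the two autoregulatory links free (cross-regulation
#' fixed from perturbation experiments) it yields the 3^2 = 9 candidate
#' topologies used for model selection.
#'
#' @param free_links Character vector naming the links to enumerate (subset
#'   of `c("er_auto", "gata3_to_er", "er_to_gata3", "gata3_auto")`).
#' @param fixed_signs Named character vector of signs for the remaining
#'   links. `free_links` and `names(fixed_signs)` must partition the four
#'   links.
#' @return A tibble with one row per topology, a character column per link,
#'   a `label` column and a list-column `topology` of [topology()] objects.
#'   Ordering is deterministic: lexicographic by link index with sign order
#'   `+`, `-`, `0`.
#' @examples
#' nrow(enumerate_topologies())  # 81
#' enumerate_topologies(
#'   free_links = c("er_auto", "gata3_auto"),
#'   fixed_signs = c(gata3_to_er = "+", er_to_gata3 = "-")
#' )
#' @export
enumerate_topologies <- function(free_links = LINKS, fixed_signs = character(0)) {
  free_links <- unique(as.character(free_links))
  if (!all(free_links %in% LINKS)) {
    abort("Unknown link name in `free_links`.", class = "ergnet_config_error")
  }
  fixed <- vapply(fixed_signs, normalize_sign, character(1))
  if (length(intersect(free_links, names(fixed))) > 0) {
    abort("A link cannot be both free and fixed.", class = "ergnet_config_error")
  }
  if (!setequal(c(free_links, names(fixed)), LINKS)) {
    abort("`free_links` and `fixed_signs` must partition the four links.",
          class = "ergnet_config_error")
  }
  choices <- lapply(setNames(LINKS, LINKS), function(l) {
    if (l %in% free_links) SIGNS else fixed[[l]]
  })
  grid <- rev(expand.grid(rev(lapply(choices, factor, levels = SIGNS)),
                          stringsAsFactors = FALSE))
  grid <- tibble::as_tibble(lapply(grid, as.character))
  grid$topology <- purrr::pmap(grid[LINKS], topology)
  grid$label <- vapply(grid$topology, format, character(1))
  grid[, c(LINKS, "label", "topology")]
}

# fold-change bound implied by a sign, used by fitting and validation
sign_fold_range <- function(sign) {
  switch(sign,
    "+" = c(1 + 1e-3, 50),
    "-" = c(0.02, 1 - 1e-3),
    "0" = c(1, 1)
  )
}

sign_of_fold <- function(f) ifelse(f > 1, "+", ifelse(f < 1, "-", "0"))
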