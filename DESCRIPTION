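Package: ergnet
Title: Topology Inference and Noise Analysis for the ERalpha-GATA3 Regulatory Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dimensionless two-gene ordinary differential equation model of the
    ERalpha-GATA3 transcriptional network with multiplicative Hill regulation.
    Provides exhaustive sign-topology enumeration, multi-start least-squares
    fitting to siRNA depletion and cycloheximide-recovery protein time courses,
    logarithmic-gain and link-elimination analyses of regulatory strength,
    steady-state ICI 182,780 dose-response topology discrimination, and
    intrinsic (Linear Noise Approximation, validated against exact stochastic
    simulation) and extrinsic (parameter ensemble) noise analysis of negative
    feedback. Includes a calibrated synthetic-data generator emulating
    western-blot and qPCR readouts so that the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    patchwork
Config/testthat/edition: 3
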