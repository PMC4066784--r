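# Shared fixtures, all generated in code.

# all-null topology parameter set (independent birth-death processes)
null_params <- function(b_e = 0.3, b_g = 0.25, k_e = 0.3, k_g = 0.25) {
  model_params(b_e = b_e, b_g = b_g, k_e = k_e, k_g = k_g,
               f = c(1, 1, 1, 1))
}

all_null_topology <- function() topology("0", "0", "0", "0")

# toy mutual-activation network: bistable by construction
bistable_params <- function() {
  normalize_to_wt(model_params(k_e = 0.3, k_g = 0.3,
                               f = c(1, 10, 10, 1),
                               K = c(1, 0.5, 0.5, 1),
                               n = c(1, 4, 4, 1)))
}

# ground-truth variants with altered GATA3 autoregulation (for sign-recovery
# checks; endpoints deliberately uncalibrated)
gata3_auto_variant <- function(sign = "0") {
  gt <- default_ground_truth()
  gt$params$f["gata3_auto"] <- switch(sign, "0" = 1, "+" = 6, "-" = 0.3)
  gt$params <- normalize_to_wt(gt$params)
  gt$topology <- implied_topology(gt$params)
  gt
}

# Random wild-type-normalized parameter set; NULL unless (1,1) is the unique
# stable fixed point AND the operating point sits in the weakly nonlinear
# regime where the Gaussian (linear-noise) description applies: local link
# gains bounded (|LG| <= 1 for cross links, self-activation gain <= 0.5 —
# stronger self-activation drives stochastic excursions that no linearized
# treatment captures).
random_stable_system <- function(seed, omega = 500) {
  set.seed(seed)
  signs <- sample(c("+", "-", "0"), 4, replace = TRUE)
  f <- vapply(signs, function(s) {
    switch(s,
           "+" = 10^stats::runif(1, log10(1.2), log10(30)),
           "-" = 10^stats::runif(1, log10(0.05), log10(0.8)),
           "0" = 1)
  }, numeric(1))
  p <- model_params(
    k_e = 10^stats::runif(1, log10(0.05), log10(1.2)),
    k_g = 10^stats::runif(1, log10(0.05), log10(1.2)),
    f = f, K = 10^stats::runif(4, log10(0.3), log10(5)),
    n = stats::runif(4, 1, 4))
  p <- normalize_to_wt(p)
  lg <- vapply(1:4, function(j) log_gain(1, p$f[j], p$K[j], p$n[j]),
               numeric(1))
  if (lg[1] > 0.5 || lg[4] > 0.5) return(NULL)
  if (any(abs(lg) > 1)) return(NULL)
  ss <- tryCatch(steady_states(p), error = function(e) NULL)
  if (is.null(ss) || sum(ss$stable) != 1) return(NULL)
  if (abs(ss$e[ss$stable] - 1) > 1e-8 || abs(ss$g[ss$stable] - 1) > 1e-8) {
    return(NULL)
  }
  stochastic_system(p, omega = omega)
}

# finite-difference logarithmic gain (independent of the closed form)
fd_log_gain <- function(x, f, K, n, h = 1e-6) {
  (log(hill_fold(x * exp(h), f, K, n)) -
     log(hill_fold(x * exp(-h), f, K, n))) / (2 * h)
}
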