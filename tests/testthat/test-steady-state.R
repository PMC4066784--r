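# independent oracle: when ERalpha autoregulation is null the e-nullcline is
# explicit, e = b_e F2(g) / k_e, so fixed points are roots of
# g - b_g F3(e(g)) F4(g) / k_g on a dense 1-D grid
nullcline_roots_1d <- function(p, sc = list(se = 1, sg = 1, ici_act = 1,
                                            k_loss = 0), gmax = 10,
                               n_grid = 20000) {
  g <- seq(1e-9, gmax, length.out = n_grid)
  e_of_g <- sc$se * p$b_e * hill_fold(g, p$f[2], p$K[2], p$n[2]) /
    (p$k_e + sc$k_loss)
  h <- sc$sg * p$b_g * hill_fold(e_of_g * sc$ici_act, p$f[3], p$K[3], p$n[3]) *
    hill_fold(g, p$f[4], p$K[4], p$n[4]) - p$k_g * g
  ix <- which(h[-1] * h[-n_grid] < 0)
  roots_g <- vapply(ix, function(i) {
    # bisection refinement
    lo <- g[i]; hi <- g[i + 1]
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      e_m <- sc$se * p$b_e * hill_fold(mid, p$f[2], p$K[2], p$n[2]) /
        (p$k_e + sc$k_loss)
      hm <- sc$sg * p$b_g *
        hill_fold(e_m * sc$ici_act, p$f[3], p$K[3], p$n[3]) *
        hill_fold(mid, p$f[4], p$K[4], p$n[4]) - p$k_g * mid
      if (sign(hm) == sign(h[i])) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  cbind(e = sc$se * p$b_e * hill_fold(roots_g, p$f[2], p$K[2], p$n[2]) /
          (p$k_e + sc$k_loss),
        g = roots_g)
}

test_that("the decoupled linear system has its single analytic fixed point", {
  p <- null_params(b_e = 0.45, b_g = 0.5, k_e = 0.3, k_g = 0.25)
  ss <- steady_states(p)
  expect_equal(nrow(ss), 1)
  expect_true(ss$stable)
  expect_equal(ss$e, 0.45 / 0.3, tolerance = 1e-9)
  expect_equal(ss$g, 0.5 / 0.25, tolerance = 1e-9)
})

test_that("grid-seeded search finds every nullcline intersection (bistable toy)", {
  p <- bistable_params()
  ss <- steady_states(p)
  oracle <- nullcline_roots_1d(p)
  expect_equal(nrow(ss), nrow(oracle))
  expect_gt(nrow(ss), 1)        # mutual activation creates extra states
  expect_equal(sum(ss$stable), 2)
  o <- order(oracle[, "g"])
  expect_equal(ss$g[order(ss$g)], unname(oracle[o, "g"]), tolerance = 1e-5)
  expect_equal(ss$e[order(ss$g)], unname(oracle[o, "e"]), tolerance = 1e-5)
})

test_that("fixed-point count matches the nullcline oracle on random systems", {
  set.seed(31)
  checked <- 0
  for (i in 1:40) {
    f <- c(1,  # keep the e-nullcline explicit for the oracle
           10^stats::runif(1, log10(0.1), log10(20)),
           10^stats::runif(1, log10(0.1), log10(20)),
           10^stats::runif(1, log10(0.1), log10(20)))
    p <- try(normalize_to_wt(model_params(
      k_e = stats::runif(1, 0.05, 1), k_g = stats::runif(1, 0.05, 1),
      f = f, K = 10^stats::runif(4, log10(0.2), log10(5)),
      n = stats::runif(4, 1, 4))), silent = TRUE)
    if (inherits(p, "try-error")) next
    ss <- try(steady_states(p), silent = TRUE)
    if (inherits(ss, "try-error")) next
    oracle <- nullcline_roots_1d(p)
    # both searches are confined to the same box; skip boundary-straddlers
    if (any(oracle[, "e"] > 9 | oracle[, "g"] > 9)) next
    expect_equal(nrow(ss), nrow(oracle), info = paste("seed case", i))
    expect_equal(sort(ss$g), sort(unname(oracle[, "g"])), tolerance = 1e-4)
    checked <- checked + 1
  }
  expect_gt(checked, 25)
})

test_that("the calibrated network is monostable under every study condition", {
  for (variant in c("0", "+", "-")) {
    gt <- default_ground_truth(variant)
    for (target in c("none", "er", "gata3")) {
      ss <- steady_states(gt$params, condition = perturbation(target, 0.9))
      expect_equal(sum(ss$stable), 1,
                   info = paste("variant", variant, "siRNA", target))
    }
  }
})

test_that("long-horizon integration lands on the root-finder's fixed point", {
  gt <- default_ground_truth()
  cond <- perturbation("gata3", 0.9)
  ss <- steady_states(gt$params, condition = cond)
  tr <- ergnet:::sim_matrix(ergnet:::theta_vec(gt$params), cond, c(0, 2000))
  expect_equal(unname(tr[2, ]), c(ss$e[ss$stable], ss$g[ss$stable]),
               tolerance = 1e-6)
})

test_that("an undersized search box raises a search failure", {
  gt <- default_ground_truth()
  expect_error(steady_states(gt$params, box = 0.05),
               class = "ergnet_search_failure")
})
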