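test_that("wild-type normalization fixes (1,1) as an exact steady state", {
  p <- model_params(k_e = 0.2, f = c(1, 1, 1, 1))
  expect_equal(normalize_to_wt(p)$b_e, 0.2)
  # F2(1) = (1 + 4)/2 with f2 = 4, K2 = 1, n2 = 1
  p2 <- model_params(k_e = 0.1, f = c(1, 4, 1, 1), K = rep(1, 4),
                     n = c(2, 1, 2, 2))
  expect_equal(normalize_to_wt(p2)$b_e, 0.04)
  # idempotence
  gt <- default_ground_truth()
  expect_equal(normalize_to_wt(gt$params), gt$params)
  # derivatives vanish at the normalized wild type
  d <- derivatives(c(e = 1, g = 1), gt$params, gt$topology)
  expect_true(all(abs(d) < 1e-10))
})

test_that("derivatives reduce to known limits", {
  p <- null_params()
  d <- derivatives(c(e = 0.4, g = 0.7), p)
  expect_equal(d[["e"]], 0.3 - 0.3 * 0.4)
  expect_equal(d[["g"]], 0.25 - 0.25 * 0.7)
  # inside a cycloheximide window synthesis is off regardless of regulation
  gt <- default_ground_truth()
  d2 <- derivatives(c(e = 0.4, g = 0.7), gt$params,
                    condition = perturbation(chx_window = c(0, 15)), time = 5)
  expect_equal(d2[["e"]], -gt$params$k_e * 0.4)
  expect_equal(d2[["g"]], -gt$params$k_g * 0.7)
})

test_that("simulate_network reproduces closed-form solutions", {
  p <- null_params(b_e = 0.36, b_g = 0.5, k_e = 0.3, k_g = 0.25)
  tt <- seq(0, 30, by = 1.5)
  # pure decay under cycloheximide
  tr <- simulate_network(p, condition = perturbation(chx_window = c(0, 30)),
                         times = tt, init = c(0.8, 1.3))
  er <- tr$level[tr$species == "er"]
  expect_equal(er, 0.8 * exp(-0.3 * tt), tolerance = 1e-6)
  g <- tr$level[tr$species == "gata3"]
  expect_equal(g, 1.3 * exp(-0.25 * tt), tolerance = 1e-6)
  # saturating growth from zero for the decoupled linear system
  tr2 <- simulate_network(p, times = tt, init = c(0, 0))
  er2 <- tr2$level[tr2$species == "er"]
  expect_equal(er2, (0.36 / 0.3) * (1 - exp(-0.3 * tt)), tolerance = 1e-6)
})

test_that("compiled integrator agrees with lsoda across conditions", {
  skip_if_not_installed("deSolve")
  gt <- default_ground_truth()
  conds <- list(perturbation("gata3", 0.9), perturbation("er", 0.9),
                perturbation("none", chx_window = c(10, 25)),
                perturbation(ici_dose = 10))
  tt <- seq(0, 48, by = 4)
  for (cond in conds) {
    mine <- ergnet:::sim_matrix(ergnet:::theta_vec(gt$params), cond, tt)
    f <- function(t, y, parms) {
      in_chx <- !is.null(cond$chx_window) && t >= cond$chx_window[1] &&
        t < cond$chx_window[2]
      sc <- ergnet:::cond_scalars(cond, in_chx)
      p <- gt$params
      ea <- max(y[1], 0) * sc$ici_act
      list(c(sc$se * p$b_e * hill_fold(ea, p$f[1], p$K[1], p$n[1]) *
               hill_fold(max(y[2], 0), p$f[2], p$K[2], p$n[2]) -
               (p$k_e + sc$k_loss) * y[1],
             sc$sg * p$b_g * hill_fold(ea, p$f[3], p$K[3], p$n[3]) *
               hill_fold(max(y[2], 0), p$f[4], p$K[4], p$n[4]) -
               p$k_g * y[2]))
    }
    ref <- deSolve::lsoda(c(1, 1), tt, f, NULL, rtol = 1e-10, atol = 1e-12)
    expect_equal(mine[, 1], unname(ref[, 2]), tolerance = 1e-5)
    expect_equal(mine[, 2], unname(ref[, 3]), tolerance = 1e-5)
  }
})

test_that("trajectories stay non-negative from non-negative starts", {
  set.seed(99)
  for (i in 1:12) {
    sys <- random_stable_system(seed = 3000 + i)
    if (is.null(sys)) next
    init <- stats::runif(2, 0, 5)
    tr <- simulate_network(sys$params, condition = perturbation("er", 0.95),
                           times = seq(0, 60, by = 2), init = init)
    expect_true(all(tr$level >= 0))
  }
})

test_that("simulate_network validates its inputs", {
  gt <- default_ground_truth()
  expect_error(simulate_network(gt$params, times = c(3, 2, 1)),
               class = "ergnet_config_error")
  expect_error(simulate_network(gt$params, times = 0:5, init = c(-1, 1)),
               class = "ergnet_config_error")
  expect_error(perturbation("both"), class = "ergnet_config_error")
  expect_error(perturbation(chx_window = c(5, 2)),
               class = "ergnet_config_error")
})

test_that("mrna proxy is 1 at the unperturbed wild type", {
  gt <- default_ground_truth()
  expect_equal(mrna_proxy(c(e = 1, g = 1), gt$params), 1)
})
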