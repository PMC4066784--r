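test_that("LNA reproduces the Poisson law exactly for the all-null topology", {
  for (omega in c(50, 500)) {
    p <- null_params(b_e = 0.36, b_g = 0.5, k_e = 0.3, k_g = 0.25)
    ns <- lna_noise(stochastic_system(p, omega = omega))
    expect_equal(ns$cv_e^2, 1 / (omega * ns$mean_e), tolerance = 1e-12)
    expect_equal(ns$cv_g^2, 1 / (omega * ns$mean_g), tolerance = 1e-12)
    expect_equal(ns$covariance[1, 2], 0, tolerance = 1e-15)
  }
})

test_that("LNA covariance is symmetric positive semidefinite", {
  checked <- 0
  s <- 0
  while (checked < 3 && s < 100) {
    s <- s + 1
    sys <- random_stable_system(seed = 6000 + s)
    if (is.null(sys)) next
    checked <- checked + 1
    ns <- lna_noise(sys)
    C <- ns$covariance
    expect_equal(C[1, 2], C[2, 1])
    expect_true(all(eigen(C, only.values = TRUE)$values > -1e-15))
  }
  expect_equal(checked, 3)
})

test_that("LNA CVs scale exactly as one over the square root of omega", {
  gt <- default_ground_truth()
  n1 <- lna_noise(stochastic_system(gt$params, omega = 200))
  n2 <- lna_noise(stochastic_system(gt$params, omega = 800))
  expect_equal(n1$cv_e / n2$cv_e, 2, tolerance = 1e-10)
  expect_equal(n1$cv_g / n2$cv_g, 2, tolerance = 1e-10)
})

test_that("LNA refuses multistable systems", {
  expect_error(lna_noise(stochastic_system(bistable_params(), omega = 500)),
               class = "ergnet_lna_invalid")
})

test_that("stochastic simulation matches Poisson statistics for null links", {
  p <- null_params(b_e = 0.3, b_g = 0.25)  # stationary count = omega
  sys <- stochastic_system(p, omega = 100)
  ssa <- gillespie_sim(sys, t_end = 3000, seed = 21, sample_dt = 0.5)
  post <- ssa$samples[ssa$samples$time_h >= 600, ]
  expect_equal(mean(post$e_count), 100, tolerance = 0.05)
  expect_equal(stats::var(post$e_count), 100, tolerance = 0.25)
  expect_equal(mean(post$g_count), 100, tolerance = 0.05)
})

test_that("stochastic simulation is a pure death process under translation block", {
  p <- null_params(k_e = 0.3, k_g = 0.5)
  sys <- stochastic_system(p, omega = 400)
  cond <- perturbation(chx_window = c(0, 3))
  finals <- vapply(1:150, function(s) {
    m <- gillespie_sim(sys, cond, t_end = 3, seed = 3000 + s, sample_dt = 3,
                       init = c(1, 1))
    m$samples$e_count[2]
  }, numeric(1))
  # binomial thinning: mean N0 p, variance N0 p(1-p) with p = exp(-k t)
  p_surv <- exp(-0.3 * 3)
  se <- sqrt(400 * p_surv * (1 - p_surv) / 150)
  expect_lt(abs(mean(finals) - 400 * p_surv), 4 * se)
})

test_that("stochastic simulation is seed-reproducible", {
  sys <- stochastic_system(default_ground_truth()$params, omega = 300)
  a <- gillespie_sim(sys, t_end = 50, seed = 5)
  b <- gillespie_sim(sys, t_end = 50, seed = 5)
  expect_identical(a$samples, b$samples)
  c <- gillespie_sim(sys, t_end = 50, seed = 6)
  expect_false(identical(a$samples, c$samples))
})

test_that("LNA agrees with the stochastic oracle for the calibrated network", {
  sys <- stochastic_system(default_ground_truth()$params, omega = 500)
  ln <- lna_noise(sys)
  ssa <- gillespie_sim(sys, t_end = 6000, seed = 2, sample_dt = 1)
  z <- (ssa$summary$cv - c(ln$cv_e, ln$cv_g)) / ssa$summary$cv_se
  expect_true(all(abs(z) < 3))
})

test_that("controlled removal preserves means and perturbs noise", {
  gt <- default_ground_truth()
  sys <- stochastic_system(gt$params, omega = 500)
  wt <- lna_noise(sys)
  # removing a link whose fold is already 1 changes nothing
  same <- remove_link_controlled(sys, "er_auto")
  expect_equal(same$params, gt$params)
  for (link in c("gata3_to_er", "er_to_gata3")) {
    removed <- remove_link_controlled(sys, link)
    expect_equal(removed$params$f[[link]], 1)
    ss <- steady_states(removed$params)
    expect_equal(ss$e[ss$stable], 1, tolerance = 1e-6)
    expect_equal(ss$g[ss$stable], 1, tolerance = 1e-6)
    nr <- lna_noise(removed)
    expect_gt(max(abs(c(nr$cv_e / wt$cv_e, nr$cv_g / wt$cv_g) - 1)), 0.01)
  }
})

test_that("extrinsic noise propagates parameter variability exactly for null links", {
  p <- null_params()
  sys <- stochastic_system(p, omega = 500)
  ens <- extrinsic_noise(sys, parameter_cv = 0.1, n_samples = 2000, seed = 9,
                         vary = "b_e")
  # steady-state e = b_e/k_e, so the ensemble CV equals the parameter CV
  expect_equal(ens$cv_e, 0.1, tolerance = 0.15)
  expect_lt(ens$cv_g, 1e-12)
  small <- extrinsic_noise(sys, parameter_cv = 0.01, n_samples = 500,
                           seed = 9, vary = "b_e")
  expect_lt(small$cv_e, 0.02)
})

test_that("extrinsic noise rises in the feedback-broken network", {
  sys <- stochastic_system(default_ground_truth()$params, omega = 500)
  wt <- extrinsic_noise(sys, parameter_cv = 0.1, n_samples = 400, seed = 30)
  broken <- remove_link_controlled(sys, "er_to_gata3")
  nb <- extrinsic_noise(broken, parameter_cv = 0.1, n_samples = 400, seed = 30)
  expect_gt(nb$cv_e, wt$cv_e)
})

test_that("extrinsic noise validates its configuration", {
  sys <- stochastic_system(default_ground_truth()$params)
  expect_error(extrinsic_noise(sys, parameter_cv = 0.7),
               class = "ergnet_config_error")
  expect_error(extrinsic_noise(sys, parameter_cv = 0.1, n_samples = 10),
               class = "ergnet_config_error")
})

test_that("omega calibration inverts the Poisson law and round-trips", {
  p <- null_params(b_e = 0.3, b_g = 0.25)  # means exactly 1
  sys <- stochastic_system(p, omega = 1)
  expect_equal(calibrate_omega(sys, c(er = 0.05)), 1 / 0.05^2,
               tolerance = 1e-10)
  expect_equal(calibrate_omega(sys, c(er = 0.1)), calibrate_omega(sys, c(er = 0.05)) / 4,
               tolerance = 1e-10)
  # joint-target round trip on the regulated network
  gt <- default_ground_truth()
  ref <- lna_noise(stochastic_system(gt$params, omega = 350))
  om <- calibrate_omega(stochastic_system(gt$params, omega = 1),
                        c(er = ref$cv_e, gata3 = ref$cv_g))
  expect_equal(om, 350, tolerance = 1e-8)
  back <- lna_noise(stochastic_system(gt$params, omega = om))
  expect_equal(back$cv_e, ref$cv_e, tolerance = 1e-8)
})
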