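test_that("zero-noise generation is exactly the deterministic model", {
  cfg <- generator_config(noise_cv = 0, n_replicates = 1, seed = 4)
  dep <- generate_depletion_timecourses(cfg)
  gt <- cfg$ground_truth
  for (cond in list(c("control", "none"), c("si_er", "er"),
                    c("si_gata3", "gata3"))) {
    tr <- simulate_network(gt$params, gt$topology,
                           perturbation(cond[2], 0.9),
                           times = cfg$depletion_times)
    obs <- dplyr::filter(dep, condition == cond[1]) |>
      dplyr::arrange(species, time_h)
    ref <- dplyr::arrange(tr, species, time_h)
    expect_equal(obs$level, ref$level, tolerance = 1e-10)
    expect_true(all(obs$sd == 0))
  }
})

test_that("recovery phases start from the cycloheximide-decayed levels", {
  cfg <- generator_config(noise_cv = 0, n_replicates = 1, seed = 4)
  dep <- generate_depletion_timecourses(cfg)
  rec <- generate_recovery_timecourses(cfg)
  k <- c(er = cfg$ground_truth$params$k_e, gata3 = cfg$ground_truth$params$k_g)
  for (cond in unique(dep$condition)) {
    for (sp in c("er", "gata3")) {
      d48 <- dep$level[dep$condition == cond & dep$species == sp &
                         dep$time_h == 48]
      r0 <- rec$level[rec$condition == cond & rec$species == sp &
                        rec$time_h == 0]
      expect_equal(r0, d48 * exp(-k[[sp]] * 15), tolerance = 1e-6)
    }
  }
})

test_that("generation is seed-reproducible and seed-sensitive", {
  a <- generate_timecourses(generator_config(seed = 6))
  b <- generate_timecourses(generator_config(seed = 6))
  expect_identical(a, b)
  c <- generate_timecourses(generator_config(seed = 7))
  expect_false(identical(a$level, c$level))
})

test_that("replicate scatter scales linearly with the configured noise CV", {
  msd <- vapply(c(0.05, 0.1, 0.2), function(cv) {
    d <- generate_depletion_timecourses(
      generator_config(noise_cv = cv, n_replicates = 8, seed = 9))
    mean(d$sd / pmax(d$level, 1e-9))
  }, numeric(1))
  expect_equal(msd[2] / msd[1], 2, tolerance = 0.3)
  expect_equal(msd[3] / msd[2], 2, tolerance = 0.3)
})

test_that("knockdown endpoints reproduce the measured population shifts", {
  dep <- generate_depletion_timecourses(
    generator_config(noise_cv = 0.1, n_replicates = 3, seed = 10))
  er_end <- dep$level[dep$condition == "si_gata3" & dep$species == "er" &
                        dep$time_h == 48]
  g_end <- dep$level[dep$condition == "si_er" & dep$species == "gata3" &
                       dep$time_h == 48]
  # ~50% ERalpha drop under GATA3 knockdown, ~15% GATA3 rise under ERalpha
  # knockdown, within measurement noise (CV 0.1, 3 replicates)
  expect_lt(abs(er_end - 0.5), 3 * 0.1 * 0.5 / sqrt(3))
  expect_lt(abs(g_end - 1.15), 3 * 0.1 * 1.15 / sqrt(3))
})

test_that("recovery under GATA3 depletion separates ERalpha autoregulation signs", {
  curves <- lapply(c("0", "+", "-"), function(s) {
    gt <- default_ground_truth(s)
    m <- ergnet:::sim_recovery_matrix(ergnet:::theta_vec(gt$params),
                                      perturbation("gata3", 0.9),
                                      c(0, 2, 4, 6, 8, 10))
    m[, 1]
  })
  expect_gt(max(abs(curves[[2]] - curves[[1]])), 0.04)
  expect_gt(max(abs(curves[[3]] - curves[[1]])), 0.04)
  expect_gt(max(abs(curves[[3]] - curves[[2]])), 0.08)
})

test_that("dose-response generation is anchored and direction-correct", {
  cfg0 <- generator_config(noise_cv = 0, n_replicates = 1, seed = 4)
  dr <- generate_dose_response(cfg0)
  expect_equal(dr$level[dr$dose_nM == 0], 1)
  expect_true(all(diff(dr$level) > -1e-9))  # null truth: non-decreasing
  cfgp <- generator_config(ground_truth = default_ground_truth("+"),
                           noise_cv = 0, n_replicates = 1, seed = 4)
  drp <- generate_dose_response(cfgp)
  expect_true(all(diff(drp$level) < 1e-9))  # positive truth: non-increasing
  expect_error(generate_dose_response(cfg0, doses = c(1, 10)),
               class = "ergnet_config_error")
})

test_that("generator configuration is validated", {
  expect_error(generator_config(noise_cv = 0.9), class = "ergnet_config_error")
  expect_error(generator_config(n_replicates = 0), class = "ergnet_config_error")
})
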