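# closed-form fit error for an all-null ground truth: every phase is a linear
# birth-death relaxation, so simulated levels have analytic expressions
closed_form_error <- function(data, p, eff = 0.9, sd_floor = 0.05,
                              t_sirna = 48, t_chx = 15) {
  lvl <- function(cond, phase, time, species) {
    k <- if (species == "er") p$k_e else p$k_g
    s <- 1
    if ((cond == "si_er" && species == "er") ||
        (cond == "si_gata3" && species == "gata3")) s <- 1 - eff
    if (phase == "depletion") {
      s + (1 - s) * exp(-k * time)
    } else {
      dep <- s + (1 - s) * exp(-k * t_sirna)
      y0 <- dep * exp(-k * t_chx)
      s + (y0 - s) * exp(-k * time)
    }
  }
  sim <- mapply(lvl, data$condition, data$phase, data$time_h, data$species)
  sum(((sim - data$level) / pmax(data$sd, sd_floor))^2)
}

noise_free_config <- function(gt = default_ground_truth()) {
  generator_config(ground_truth = gt, noise_cv = 0, n_replicates = 1, seed = 5)
}

test_that("fit error vanishes on self-generated noise-free data", {
  gt <- default_ground_truth()
  data <- generate_timecourses(noise_free_config(gt))
  expect_lt(fit_error(data, gt$params, gt$topology), 1e-8)
})

test_that("fit error matches the linear closed form for an all-null truth", {
  p <- null_params(b_e = 0.3, b_g = 0.25)  # b = k: wild type at (1,1)
  data <- generate_timecourses(
    generator_config(ground_truth = list(topology = all_null_topology(),
                                         params = p),
                     noise_cv = 0.1, n_replicates = 3, seed = 8))
  expect_equal(fit_error(data, p), closed_form_error(data, p),
               tolerance = 1e-7)
})

test_that("the truth is a local minimum of the error on noise-free data", {
  gt <- default_ground_truth()
  data <- generate_timecourses(noise_free_config(gt))
  e0 <- fit_error(data, gt$params)
  for (pert in list(c("k_e", 1.5), c("k_g", 1.5))) {
    p <- gt$params
    p[[pert[1]]] <- p[[pert[1]]] * as.numeric(pert[2])
    p <- normalize_to_wt(p)
    expect_gt(fit_error(data, p), e0)
  }
  p <- gt$params
  p$f["gata3_to_er"] <- p$f["gata3_to_er"] * 1.5
  expect_gt(fit_error(data, normalize_to_wt(p)), e0)
})

test_that("degradation rates are identified exactly from noise-free decay", {
  gt <- default_ground_truth()
  data <- generate_timecourses(noise_free_config(gt))
  k <- estimate_degradation_rates(data)
  expect_equal(unname(k), c(gt$params$k_e, gt$params$k_g), tolerance = 1e-6)
})

test_that("refitting the true topology recovers the parameters", {
  gt <- default_ground_truth()
  data <- generate_timecourses(noise_free_config(gt))
  fit <- fit_topology(data, gt$topology, n_starts = 60, seed = 2)
  expect_lt(fit$results$error[1], 1e-6)
  best <- best_params(fit)
  for (j in c("gata3_to_er", "er_to_gata3", "gata3_auto")) {
    expect_equal(unname(best$f[j]), unname(gt$params$f[j]), tolerance = 0.1)
  }
  expect_equal(best$k_e, gt$params$k_e, tolerance = 0.05)
  expect_equal(best$k_g, gt$params$k_g, tolerance = 0.05)
})

test_that("fitting is reproducible for a fixed seed", {
  gt <- default_ground_truth()
  data <- generate_timecourses(generator_config(seed = 3))
  f1 <- fit_topology(data, gt$topology, n_starts = 8, seed = 12)
  f2 <- fit_topology(data, gt$topology, n_starts = 8, seed = 12)
  expect_identical(f1$results$error, f2$results$error)
  expect_identical(f1$results$theta, f2$results$theta)
})

test_that("a freer topology never fits noise-free data materially worse", {
  gt <- default_ground_truth()
  data <- generate_timecourses(noise_free_config(gt))
  fit_true <- fit_topology(data, gt$topology, n_starts = 40, seed = 2)
  super <- topology(er_auto = "+")  # adds three free parameters
  fit_super <- fit_topology(data, super, n_starts = 60, seed = 2)
  expect_lte(fit_super$results$error[1], fit_true$results$error[1] + 0.01)
})

test_that("recovery data rank the true GATA3 autoregulation sign first", {
  # the sign-recovery property, scaled to three ground truths x three signs
  cands <- enumerate_topologies(
    free_links = "gata3_auto",
    fixed_signs = c(er_auto = "0", gata3_to_er = "+", er_to_gata3 = "-"))
  for (true_sign in c("+", "0", "-")) {
    gt <- gata3_auto_variant(true_sign)
    data <- generate_timecourses(
      generator_config(ground_truth = gt, noise_cv = 0.1, n_replicates = 3,
                       seed = 17))
    rk <- rank_topologies(data, cands, n_starts = 30, seed = 5)
    best_label <- rk$leaderboard$label[which.min(rk$leaderboard$best_error)]
    expect_equal(substr(best_label, 4, 4), true_sign)
  }
})

test_that("malformed observation tables are rejected", {
  gt <- default_ground_truth()
  data <- generate_timecourses(generator_config(seed = 3))
  expect_error(fit_error(data[, -3], gt$params), class = "ergnet_config_error")
  bad <- data
  bad$condition[1] <- "si_foxa1"
  expect_error(fit_error(bad, gt$params), class = "ergnet_config_error")
})
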