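test_that("parameter sampling has uniform marginals, target rank correlation, and is seed-reproducible", {
  cfg <- mc_config(iterations = 10000, seed = 3)
  d1 <- sample_parameters(cfg)
  d2 <- sample_parameters(cfg)
  expect_identical(d1, d2)
  # marginals stay inside the configured ranges and look uniform
  for (p in colnames(d1)) {
    r <- cfg$parameter_ranges[[p]]
    expect_true(all(d1[, p] >= r[1] & d1[, p] <= r[2]))
    if (r[2] > r[1]) {
      u <- (d1[, p] - r[1]) / (r[2] - r[1])
      expect_lt(abs(mean(u) - 0.5), 0.02)
      expect_lt(abs(stats::var(u) - 1 / 12), 0.005)
    }
  }
  # rank correlations within +-0.05 of the +0.5 / -0.5 targets
  expect_lt(abs(cor(d1[, "mu_ek"], d1[, "r"], method = "spearman") - 0.5),
            0.05)
  expect_lt(abs(cor(d1[, "mu_ek"], d1[, "q"], method = "spearman") + 0.5),
            0.05)
  expect_lt(abs(cor(d1[, "n"], d1[, "mu_ek"], method = "spearman")), 0.05)
})

test_that("zero-width ranges give constant draws and bad configs are rejected", {
  rg <- gen_parameter_ranges(rsd = c(n = 0, mu_ek = 0, r = 0, q = 0, v = 0))
  cfg <- mc_config(iterations = 200, parameter_ranges = rg$parameter_ranges)
  d <- sample_parameters(cfg)
  expect_true(all(apply(d, 2, function(z) diff(range(z)) == 0)))
  expect_error(mc_config(iterations = 10), "100")
  bad <- diag(5); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(mc_config(correlation = bad), "semi-definite")
})

test_that("slope-error distribution is degenerate without parameter variance", {
  rg <- gen_parameter_ranges(rsd = c(n = 0, mu_ek = 0, r = 0, q = 0, v = 0))
  cfg <- mc_config(iterations = 200, parameter_ranges = rg$parameter_ranges)
  mc <- run_slope_error_mc(cfg)
  expect_equal(mc$sd, 0, tolerance = 1e-15)
  nominal <- slope_stderr_model(rate_model_params(),
                                N = predict_count(rate_model_params()),
                                sum_sq_x = sum((seq(480, 880, 10) -
                                                  680)^2),
                                n_points = 41)
  expect_equal(mc$mean, nominal, tolerance = 1e-12)
})

test_that("slope-error spread scales linearly with the input range half-widths", {
  tpl <- rate_model_params(relative_sigmas = c(n = 0.2, mu_ek = 0.3,
                                               r = 0.3, q = 0.3))
  rg1 <- gen_parameter_ranges()
  rsd_half <- c(n = 0.10, mu_ek = 0.15, r = 0.15, q = 0.15, v = 0.005)
  rg2 <- gen_parameter_ranges(rsd = rsd_half)
  m1 <- run_slope_error_mc(mc_config(iterations = 4000,
                                     parameter_ranges = rg1$parameter_ranges,
                                     seed = 5), tpl)
  m2 <- run_slope_error_mc(mc_config(iterations = 4000,
                                     parameter_ranges = rg2$parameter_ranges,
                                     seed = 5), tpl)
  expect_lt(abs(m1$sd / m2$sd - 2), 0.3)   # small-perturbation linearity, 15%
})

test_that("onset distributions respond to noise as the sweep statistics require", {
  ds <- gen_sweep(noise_level = 0)
  cfg <- mc_config(iterations = 2000, seed = 9)
  d0 <- run_onset_mc(ds, 0, cfg)
  expect_equal(d0$sd, 0, tolerance = 1e-12)
  expect_true(all(d0$samples == d0$nominal_onset))
  d05 <- run_onset_mc(ds, 0.5, cfg)
  d10 <- run_onset_mc(ds, 1.0, cfg)
  # sd grows monotonically with noise and roughly linearly
  expect_gt(d05$sd, 0)
  expect_gt(d10$sd, d05$sd)
  expect_lt(abs(d10$sd / d05$sd - 2), 0.5)
  # mean onset stays at the nominal value within half a sd
  expect_lt(abs(d05$mean - d05$nominal_onset), 0.5 * d05$sd)
  expect_lt(abs(d10$mean - d10$nominal_onset), 0.5 * d10$sd)
})

test_that("distribution summaries satisfy the RSD identity and flag outliers", {
  set.seed(21)
  fake <- structure(list(samples = rnorm(10000), nominal_onset = 0,
                         noise_level = 0.1), class = "onset_distribution")
  sm <- summary(fake)
  expect_equal(sm$sd, 1, tolerance = 0.03)
  expect_equal(sm$rsd_percent, 100 * sm$sd / sm$mean)
  const <- structure(list(samples = rep(5, 100), nominal_onset = 5,
                          noise_level = 0), class = "onset_distribution")
  smc <- summary(const)
  expect_equal(smc$sd, 0)
  expect_length(smc$outliers, 0)
})
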