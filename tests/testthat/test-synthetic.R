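test_that("sweep generator is seed-deterministic and round-trips the onset", {
  d1 <- gen_sweep(noise_level = 0.3, seed = 5)
  d2 <- gen_sweep(noise_level = 0.3, seed = 5)
  expect_identical(d1$responses, d2$responses)
  d3 <- gen_sweep(noise_level = 0.3, seed = 6)
  expect_false(identical(d1$responses, d3$responses))
  expect_equal(fit_sweep(gen_sweep(noise_level = 0))$onset_voltage, 680.39,
               tolerance = 0.01)
  expect_error(gen_sweep(onset_voltage = 100), "inside")
  expect_error(gen_sweep(voltage_grid = seq(0, 800, by = 50)), "increments")
})

test_that("generated sweeps validate against the dataset invariants", {
  d <- gen_sweep(noise_level = 1.0, seed = 2)
  expect_s3_class(d, "sweep_dataset")
  expect_true(all(d$responses >= 0))
  expect_true(all(diff(d$voltages) > 0))
})

test_that("parameter ranges hit their target RSDs", {
  rg <- gen_parameter_ranges(rsd = c(n = 0.2, mu_ek = 0.3, r = 0.3,
                                     q = 0.3, v = 0.01))
  # half-width / nominal = sqrt(3) * rsd
  r <- rg$parameter_ranges$mu_ek
  nom <- rg$nominal[["mu_ek"]]
  expect_equal((r[2] - r[1]) / 2 / nom, sqrt(3) * 0.3, tolerance = 1e-12)
  rz <- gen_parameter_ranges(rsd = c(n = 0, mu_ek = 0, r = 0, q = 0, v = 0))
  expect_equal(rz$parameter_ranges$n[1], rz$parameter_ranges$n[2])
  expect_error(gen_parameter_ranges(rsd = c(n = 0.6, mu_ek = 0.3, r = 0.3,
                                            q = 0.3, v = 0.01)), "0.5")
  # empirical check on a large draw
  cfg <- mc_config(iterations = 20000, parameter_ranges = rg$parameter_ranges,
                   seed = 12)
  d <- sample_parameters(cfg)
  emp <- sd(d[, "r"]) / mean(d[, "r"])
  expect_lt(abs(emp / 0.3 - 1), 0.02)
})

test_that("transition-curve fixtures are exact erf shapes", {
  cv <- gen_transition_curve(center = 300, sigma = 25)
  ft <- fit_erf(cv)
  expect_equal(ft$center, 300, tolerance = 300 * 1e-4)
  expect_equal(ft$sigma, 25, tolerance = 25 * 1e-4)
  pr <- partial_range(cv)
  expect_equal(pr$delta, 2 * qnorm(0.95) * 25, tolerance = 0.3)
  dp <- derivative_peak(cv)
  expect_equal(dp$fwhm, 2.3548 * 25, tolerance = 0.01)
  expect_error(gen_transition_curve(0, -1), "positive")
})

test_that("generated sweeps plus the onset MC reproduce the stable-mean, growing-sd pattern", {
  ds <- gen_sweep(noise_level = 0)
  cfg <- mc_config(iterations = 400, seed = 31,
                   noise_levels = c(0.1, 0.5, 1.0))
  study <- onset_noise_study(ds, cfg)
  sds <- vapply(study, function(d) d$sd, numeric(1))
  means <- vapply(study, function(d) d$mean, numeric(1))
  expect_true(all(diff(sds) > 0))
  expect_true(all(abs(means - study[[1]]$nominal_onset) < 0.5 * sds))
  # roughly linear growth of sd across 0.1 / 0.5 / 1.0
  expect_lt(abs(sds[3] / sds[2] - 2), 0.5)
})
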