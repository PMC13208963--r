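test_that("partial range recovers the Gaussian quantile spacing on an exact erf curve", {
  # capture = Phi((x - 500)/10): 5-95% span is 2 * 1.6449 * sigma
  curve <- gen_transition_curve(center = 500, sigma = 10,
                                grid = seq(450, 550, by = 0.25))
  pr <- partial_range(curve)
  expect_equal(pr$delta, 2 * qnorm(0.95) * 10, tolerance = 1e-3)
  expect_lt(pr$x5, pr$x95)
})

test_that("partial range handles step curves and reversed orientation", {
  step <- transition_curve(seq(1, 10), c(rep(100, 5), rep(0, 5)))
  pr <- partial_range(step)
  expect_lte(pr$delta, 1)    # within one grid spacing
  up <- transition_curve(seq(1, 100),
                         100 * pnorm((seq(1, 100) - 50) / 8))
  dn <- transition_curve(seq(1, 100),
                         100 * (1 - pnorm((seq(1, 100) - 50) / 8)))
  expect_equal(partial_range(up)$delta, partial_range(dn)$delta,
               tolerance = 1e-9)
})

test_that("erf fit recovers the generating parameters", {
  curve <- gen_transition_curve(center = 500, sigma = 10)
  ft <- fit_erf(curve)
  expect_equal(ft$sigma, 10, tolerance = 1e-3)
  expect_equal(ft$center, 500, tolerance = 1e-2)
  # self-consistency between partial_range and the fitted sigma
  pr <- partial_range(curve)
  expect_equal(pr$delta / ft$sigma, 2 * qnorm(0.95), tolerance = 0.05)
})

test_that("erf fit sigma is recovered within 10% under 2% noise across replicates", {
  ok <- vapply(1:100, function(s) {
    curve <- gen_transition_curve(center = 500, sigma = 10, noise_sd = 2,
                                  seed = s)
    ft <- tryCatch(fit_erf(curve), error = function(e) NULL)
    !is.null(ft) && abs(ft$sigma - 10) / 10 < 0.10
  }, logical(1))
  expect_gt(mean(ok), 0.9)
})

test_that("derivative peak converts sigma to FWHM and variance exactly", {
  curve <- gen_transition_curve(center = 100, sigma = 10)
  dp <- derivative_peak(curve)
  expect_equal(dp$fwhm / dp$sigma, 2 * sqrt(2 * log(2)), tolerance = 1e-12)
  expect_equal(dp$fwhm, 23.548, tolerance = 1e-3)
  expect_equal(dp$variance, 100, tolerance = 1e-2)
  # the fitted derivative integrates back to the transition amplitude
  expect_equal(dp$derivative_area, dp$amplitude, tolerance = 0.01)
  # finite-difference derivative peaks at the fitted centre
  dfd <- derivative_peak(curve, method = "finite_diff")
  expect_lt(abs(dfd$peak_x - dp$center),
            max(diff(curve$x_values)))
})

test_that("4-sigma resolvability rule gives the 2.3% overlap bound", {
  r <- resolvability(delta_x = 4 * 24, sigma = 24)
  expect_true(r$resolved)
  expect_equal(r$overlap_fraction, pnorm(-2), tolerance = 1e-12)
  expect_equal(r$overlap_fraction, 0.02275, tolerance = 1e-4)
  r0 <- resolvability(0, 10)
  expect_false(r0$resolved)
  expect_equal(r0$overlap_fraction, 0.5)
  expect_false(resolvability(3.9 * 10, 10)$resolved)
  expect_error(resolvability(10, -1), "positive")
})

test_that("voltage windows map linearly to EKMr windows", {
  f <- bench_field(100)
  r <- voltage_range_to_ekmr_range(f, 200, 400)
  expect_equal(r$ekmr_hi / r$ekmr_lo, 2, tolerance = 1e-12)
  expect_error(voltage_range_to_ekmr_range(f, 400, 400), "empty")
  k <- max(ekmr_profile(f)$ekmr_Vpm2) / 100
  expect_equal(r$ekmr_lo, 200 * k, tolerance = 1e-12)
})

test_that("sweep_capture errors when no transition is bracketed", {
  f <- bench_field(100)
  par0 <- physical_params(mu_dep = 0)
  expect_error(sweep_capture(benchmark_channel(), par0, "voltage",
                             field = f), "mu_dep")
  par <- physical_params(mu_ek = 4e-9, mu_dep = -4e-19)
  vc <- predict_onset_voltage(f, par$mu_ek, par$mu_dep)
  expect_error(sweep_capture(benchmark_channel(), par, "voltage",
                             grid = vc * seq(0.01, 0.1, length.out = 8),
                             field = f, refine = FALSE),
               "not bracketed")
})
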