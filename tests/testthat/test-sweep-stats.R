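test_that("rate-model routes agree algebraically at random parameter sets", {
  set.seed(42)
  for (i in 1:20) {
    n <- 10^runif(1, 11, 14)
    mu <- 10^runif(1, -9.5, -8)
    R <- 10^runif(1, 8, 10)
    i_ave <- 10^runif(1, -8, -6)
    t <- runif(1, 10, 120)
    w <- runif(1, 1e-4, 5e-4); h <- runif(1, 1e-5, 5e-5)
    L <- runif(1, 0.01, 0.05)
    p <- rate_model_params(n = n, mu_ek = mu, r_ave = R,
                           q_charge = i_ave * t, i_ave = i_ave, t = t,
                           w = w, h = h, L = L)
    N <- predict_count(p, "charge")
    expect_equal(predict_count(p, "kinematic") / N, 1, tolerance = 1e-12)
    expect_equal(predict_count(p, "current") / N, 1, tolerance = 1e-12)
  }
})

test_that("count prediction has the expected proportionalities and identity point", {
  unit <- rate_model_params(n = 1, mu_ek = 1, r_ave = 1, q_charge = 1,
                            t = 1, w = 1, h = 1, L = 1)
  expect_equal(predict_count(unit), 1)
  p <- rate_model_params()
  p2 <- rate_model_params(n = 2 * p$n)
  expect_equal(predict_count(p2), 2 * predict_count(p))
  p3 <- rate_model_params(L = 2 * p$L)
  expect_equal(predict_count(p3), predict_count(p) / 2)
  expect_error(rate_model_params(n = -1), "non-positive")
})

test_that("count error propagation follows the quadrature formula", {
  p0 <- rate_model_params(relative_sigmas = c(n = 0, mu_ek = 0, r = 0, q = 0))
  expect_equal(propagate_sigma_n(p0, N = 100), 0)
  p4 <- rate_model_params(relative_sigmas = c(n = 0.1, mu_ek = 0.1,
                                              r = 0.1, q = 0.1))
  expect_equal(propagate_sigma_n(p4, N = 100), 20, tolerance = 1e-12)
  p3 <- rate_model_params(relative_sigmas = c(n = 0.3, mu_ek = 0.3,
                                              r = 0.3, q = 0))
  expect_equal(propagate_sigma_n(p3, N = 1), sqrt(3 * 0.09),
               tolerance = 1e-12)
})

test_that("regression slope error matches lm's estimate on random data", {
  set.seed(7)
  for (i in 1:5) {
    x <- sort(runif(12, 0, 100))
    y <- 2 * x + rnorm(12, 0, 5)
    d <- sweep_dataset(x, pmax(y, 0))
    s_pkg <- slope_stderr_regression(d)
    s_lm <- summary(lm(pmax(y, 0) ~ x))$coefficients["x", "Std. Error"]
    expect_equal(s_pkg, s_lm, tolerance = 1e-10)
  }
  # perfectly linear data: zero slope error
  d0 <- sweep_dataset(1:5, 2 * (1:5))
  expect_equal(slope_stderr_regression(d0), 0, tolerance = 1e-12)
  # hand-computed oracle: y = x with residuals -1,+1,-1,+1 on x = 1..4
  dh <- sweep_dataset(1:4, c(0, 3, 2, 5))
  # OLS on these points: slope 1.4, intercept -1; rss and sxx by hand
  xh <- 1:4; yh <- c(0, 3, 2, 5)
  a <- 1.4; b <- -1
  s_hand <- sqrt(sum((yh - (a * xh + b))^2) / 2 / sum((xh - 2.5)^2))
  expect_equal(slope_stderr_regression(dh), s_hand, tolerance = 1e-12)
})

test_that("model slope error is linear in chi and zero at chi = 0", {
  p <- rate_model_params(chi = 1,
                         relative_sigmas = c(n = 0.2, mu_ek = 0.3,
                                             r = 0.3, q = 0.3))
  s1 <- slope_stderr_model(p, N = 200, sum_sq_x = 2.6e5, n_points = 41)
  p2 <- p; p2$chi <- 2
  expect_equal(slope_stderr_model(p2, N = 200, sum_sq_x = 2.6e5,
                                  n_points = 41), 2 * s1)
  p0 <- p; p0$chi <- 0   # direct field edit bypasses the positivity check
  expect_equal(slope_stderr_model(p0, N = 200, sum_sq_x = 2.6e5,
                                  n_points = 41), 0)
  # literal and squared variants differ by sqrt(N * sum rel^2) / ... ratio
  s_sq <- slope_stderr_model(p, N = 200, sum_sq_x = 2.6e5, n_points = 41,
                             mode = "squared")
  expect_equal(s_sq / s1, sqrt(200), tolerance = 1e-9)
})

test_that("sweep fitting recovers exact onsets and respects invariances", {
  v <- seq(500, 900, by = 10)
  d <- sweep_dataset(v, pmax(0, 1.7 * (v - 680)))
  ft <- fit_sweep(d)
  expect_equal(ft$onset_voltage, 680, tolerance = 1e-9)
  # intercept identity: onset = 0 when y_baseline equals the intercept
  ft2 <- fit_sweep(d, y_baseline = ft$intercept)
  expect_equal(ft2$onset_voltage, 0, tolerance = 1e-9)
  # onset invariant under positive rescaling of the response
  d2 <- sweep_dataset(v, 3.7 * pmax(0, 1.7 * (v - 680)))
  expect_equal(fit_sweep(d2)$onset_voltage, ft$onset_voltage,
               tolerance = 1e-9)
  # generator round-trip at the anchor onset
  expect_equal(fit_sweep(gen_sweep(noise_level = 0))$onset_voltage,
               680.39, tolerance = 0.01)
  # non-capturing sweep: onset undefined
  dd <- sweep_dataset(v, rev(pmax(0, 1.7 * (v - 680))) + 1)
  expect_error(fit_sweep(dd), "slope")
})

test_that("sweep dataset validation rejects malformed inputs", {
  expect_error(sweep_dataset(c(1, 2), c(1, 2)), "3 sweep points")
  expect_error(sweep_dataset(c(1, 2, 2), c(1, 2, 3)), "increasing")
  expect_error(sweep_dataset(1:3, c(1, -1, 2)), "non-negative")
})
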