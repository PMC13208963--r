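test_that("straight channel reproduces the uniform-field closed form", {
  st <- straight_channel(length = 0.01, width = 200e-6)
  f <- solve_potential(st, 100, resolution = 8, uniform = TRUE)
  expect_equal(unname(range(f$Emag[f$grid$mask])), c(1e4, 1e4),
               tolerance = 1e-8)
  # gradient of a uniform field vanishes (up to roundoff on E^2 ~ 1e8)
  expect_lt(max(abs(f$gradE2x), abs(f$gradE2y)) / 1e4^2, 1e-5)
  expect_lt(max(f$ekmr[f$grid$mask]) / 1e4, 1e-5)
})

test_that("field scales linearly and grad E^2 quadratically in applied voltage", {
  f1 <- bench_field(100)
  f2 <- solve_potential(benchmark_channel(), 200, resolution = 10)
  m <- f1$grid$mask
  expect_lt(max(abs(f2$Emag[m] / 2 - f1$Emag[m])) / max(f1$Emag[m]), 1e-9)
  expect_lt(max(abs(f2$gradE2x[m] / 4 - f1$gradE2x[m])) /
              max(abs(f1$gradE2x[m])), 1e-9)
  # scale_field matches an actual solve exactly
  fs <- scale_field(f1, 200)
  expect_equal(fs$Emag, f2$Emag, tolerance = 1e-12)
})

test_that("discrete maximum principle and current conservation hold on presets", {
  for (dev in c("V2L", "V2S")) {
    geo <- build_geometry(dev)
    win <- c(geo$n_gates - 2L, geo$n_gates)
    f <- solve_potential(geo, 500, resolution = 8, window = win)
    hi <- max(f$phi_window); lo <- min(f$phi_window)
    expect_gte(min(f$phi, na.rm = TRUE), lo - 1e-6 * 500)
    expect_lte(max(f$phi, na.rm = TRUE), hi + 1e-6 * 500)
    cur <- section_currents(f)
    expect_lt(diff(range(cur)) / mean(cur), 0.01)
  }
  st <- solve_potential(straight_channel(), 100, resolution = 8,
                        uniform = TRUE)
  expect_lt(diff(range(section_currents(st))) / mean(section_currents(st)),
            0.01)
})

test_that("centreline EKMr peak is grid-converged within 3% from 8 to 16 cells per gap", {
  geo <- build_geometry("V2L")
  pk <- sapply(c(8, 16), function(res) {
    f <- solve_potential(geo, 680, resolution = res,
                         window = c(25, 27))
    max(gate_peaks(f)$ekmr_peak_Vpm2)
  })
  expect_lt(abs(pk[2] / pk[1] - 1), 0.03)
})

test_that("EKMr profile peaks at the gates and scales linearly with voltage", {
  f <- bench_field(100)
  prof <- ekmr_profile(f)
  expect_true(all(prof$ekmr_Vpm2 >= 0))
  pk <- gate_peaks(f)
  expect_identical(nrow(pk), 3L)
  # peaks are near the gate positions
  expect_lt(max(abs(pk$x_peak_m - benchmark_channel()$gates$position)),
            2 * benchmark_channel()$gates$gap[1])
  f2 <- scale_field(f, 200)
  prof2 <- ekmr_profile(f2)
  expect_lt(max(abs(prof2$ekmr_Vpm2 - 2 * prof$ekmr_Vpm2)) /
              max(prof$ekmr_Vpm2), 1e-9)
})

test_that("matched-gradient calibration equalizes peak gap gradients", {
  fL <- solve_potential(build_geometry("V2L"), 680, resolution = 8,
                        window = c(25, 27))
  fS <- solve_potential(build_geometry("V2S"), 100, resolution = 8,
                        window = c(22, 24))
  mg <- match_gradient(fL, fS, 1050)
  expect_lt(abs(mg$ratio - 1), 0.05)
  expect_gt(mg$v_b, 0)
})

test_that("similitude flow is parallel to E; stokes mode gives divergence-free plug flow", {
  f <- bench_field(100)
  fl <- flow_field(f, mode = "similitude")
  m <- f$grid$mask
  cross <- abs(fl$ux * f$Ey - fl$uy * f$Ex)
  expect_lt(max(cross[m]) / max(f$E2), 1e-12)

  st <- solve_potential(straight_channel(), 100, resolution = 8,
                        uniform = TRUE)
  fs <- flow_field(st, mode = "stokes")
  slip <- st$params$mu_ek * 100 / straight_channel()$channel_length
  expect_lt(max(abs(fs$ux[st$grid$mask] / slip - 1)), 0.01)
  dv <- flow_divergence(fs, st$grid)
  expect_lt(max(abs(dv)), 1e-6)
  # zero voltage limit: velocities scale to zero with the field
  f0 <- scale_field(st, 1e-12)
  fl0 <- flow_field(f0, mode = "similitude")
  expect_lt(max(abs(fl0$ux)), 1e-12)
})
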