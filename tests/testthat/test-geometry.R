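test_that("presets reproduce the published gate counts and minimum gaps", {
  v2l <- build_geometry("V2L")
  expect_identical(v2l$n_gates, 27L)
  expect_equal(min(v2l$gates$gap), 27e-6)
  v2s <- build_geometry("V2S")
  expect_identical(v2s$n_gates, 24L)
  expect_equal(min(v2s$gates$gap), 3e-6)
  # three-gate sets with non-increasing gaps, terminal set at the minimum
  expect_true(all(diff(v2l$gates$gap) <= 0))
  expect_equal(v2l$gates$gap[25:27], rep(27e-6, 3))
  expect_equal(v2s$gates$gap[22:24], rep(3e-6, 3))
})

test_that("invalid geometries are rejected", {
  expect_error(build_geometry("V9"), "unknown")
  expect_error(build_geometry(gap_widths = c(50e-6, 0),
                              channel_length = 2e-3), "positive")
  expect_error(build_geometry(gap_widths = c(30e-6, 60e-6),
                              gate_positions = c(1e-3, 1.5e-3),
                              channel_length = 3e-3), "non-increasing")
  expect_error(build_geometry(gap_widths = 400e-6, channel_length = 2e-3,
                              channel_width = 300e-6), "smaller than")
})

test_that("halfwidth profile pinches to the gap and the resistance integral is exact on straight segments", {
  geo <- single_gate(gap = 50e-6)
  expect_equal(channel_halfwidth(geo, 1e-3), 25e-6)
  expect_equal(channel_halfwidth(geo, 0), 150e-6)
  # straight channel: R = L / (2 * halfwidth)
  st <- straight_channel(length = 1e-2, width = 200e-6)
  expect_equal(channel_resistance(st), 1e-2 / 200e-6, tolerance = 1e-12)
  # gated channel resistance exceeds the straight-channel value
  expect_gt(channel_resistance(geo),
            geo$channel_length / geo$channel_width)
})

test_that("rasterize produces a connected fluid mask and honours the resolution floor", {
  st <- straight_channel()
  g <- rasterize(st, resolution = 8, uniform = TRUE)
  expect_true(all(g$mask))
  expect_error(rasterize(st, resolution = 4), "at least 8")

  v2s <- build_geometry("V2S")
  g2 <- rasterize(v2s, resolution = 8, window = c(22, 24))
  expect_true(sum(g2$mask) > 0)
  # a gate strictly reduces fluid area relative to the straight channel
  geo1 <- single_gate(gap = 100e-6)
  geo0 <- straight_channel(length = geo1$channel_length, width = 300e-6)
  a1 <- fluid_area(rasterize(geo1, resolution = 10, uniform = TRUE))
  a0 <- fluid_area(rasterize(geo0, resolution = 10, uniform = TRUE))
  expect_lt(a1, a0)
})

test_that("geometry schema round-trips through JSON and YAML", {
  geo <- single_gate(gap = 42e-6, half_angle = 40)
  for (ext in c("json", "yaml")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_geometry(geo, path)
    back <- read_geometry(path)
    expect_equal(back$gates$gap, geo$gates$gap)
    expect_equal(back$gates$position, geo$gates$position)
    expect_equal(back$half_angle, geo$half_angle, tolerance = 1e-12)
    expect_equal(back$channel_length, geo$channel_length)
    unlink(path)
  }
})
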