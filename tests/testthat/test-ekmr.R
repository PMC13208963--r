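test_that("EKMr arithmetic and invariances", {
  expect_equal(ekmr(1e-8, -1e-18), 1e10)
  expect_equal(ekmr(3 * 1e-8, 3 * -1e-18), ekmr(1e-8, -1e-18))
  expect_error(ekmr(1e-8, 0), "non-zero")
})

test_that("device dynamic range decomposes into voltage and spatial factors", {
  f <- bench_field(100)
  dr <- device_dynamic_range(f, v_lo = 100, v_hi = 1000)
  expect_equal(dr$voltage_factor, 10)
  expect_equal(dr$ekmr_max / dr$ekmr_min,
               dr$voltage_factor * dr$spatial_factor, tolerance = 1e-12)
  expect_equal(dr$orders_of_magnitude,
               log10(dr$ekmr_max / dr$ekmr_min), tolerance = 1e-12)
  # over [V, 10V] the span is exactly one order plus the spatial term
  expect_equal(dr$orders_of_magnitude, 1 + log10(dr$spatial_factor),
               tolerance = 1e-12)
  expect_error(device_dynamic_range(f, 500, 500), "empty")
})

test_that("V2L preset spans roughly four orders of EKMr over 100-3000 V", {
  geo <- build_geometry("V2L")
  f <- solve_potential(geo, 500, resolution = 8)
  dr <- device_dynamic_range(f, 100, 3000)
  expect_gt(dr$orders_of_magnitude, 2.5)
  expect_lt(dr$orders_of_magnitude, 5.5)
})

test_that("mobility tables load, validate, and round-trip", {
  df <- data.frame(
    taxon = c("S. epidermidis", "S. aureus", "E. coli"),
    strain = c("ATCC 35984", "ATCC 43300", "O157:H7"),
    mu_ek_m2_per_Vs = c(4.0e-9, 6.2e-9, 5.1e-9),
    mu_dep_m4_per_V2s = c(-4.1e-19, -6.3e-19, -2.2e-19),
    source = c("a", "b", "c")
  )
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  rec <- load_mobility_table(path)
  expect_identical(nrow(rec), 3L)
  expect_equal(rec$ekmr_Vpm2, df$mu_ek_m2_per_Vs / abs(df$mu_dep_m4_per_V2s))

  # inconsistent stored EKMr warns; zero mobility errors
  df$ekmr_Vpm2 <- rec$ekmr_Vpm2 * c(1, 1.01, 1)
  write.csv(df, path, row.names = FALSE)
  expect_warning(load_mobility_table(path), "0.1%")
  df$mu_dep_m4_per_V2s[2] <- 0
  write.csv(df, path, row.names = FALSE)
  expect_error(load_mobility_table(path), "row")
  df2 <- df[, setdiff(names(df), "source")]
  write.csv(df2, path, row.names = FALSE)
  expect_error(load_mobility_table(path), "missing")
  unlink(path)
})

test_that("1-D collapses equal-EKMr records that 2-D separates", {
  df <- data.frame(
    taxon = c("A", "B"), strain = c("x", "y"),
    mu_ek_m2_per_Vs = c(2e-9, 4e-9),
    mu_dep_m4_per_V2s = c(-2e-19, -4e-19),
    source = "synthetic"
  )
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  rec <- load_mobility_table(path)
  unlink(path)
  one <- map_records(rec, "1d_ekmr")
  two <- map_records(rec, "2d_mobility")
  expect_equal(one$ekmr_Vpm2[1], one$ekmr_Vpm2[2])
  expect_false(two$mu_ek_m2_per_Vs[1] == two$mu_ek_m2_per_Vs[2])
  expect_equal(two$mu_ek_m2_per_Vs, df$mu_ek_m2_per_Vs)
  expect_error(map_records(rec[0, ]), "empty")
  expect_identical(nrow(map_records(rec[1, ], "1d_ekmr")), 1L)
})
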