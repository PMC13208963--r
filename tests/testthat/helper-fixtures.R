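# Shared small fixtures: tiny geometries and fields that solve in well
# under a second, built once per test run.

straight_channel <- function(length = 2e-3, width = 200e-6) {
  build_geometry(gap_widths = numeric(0), channel_length = length,
                 channel_width = width, name = "straight")
}

single_gate <- function(gap = 50e-6, width = 300e-6, length = 2e-3,
                        position = 1e-3, ...) {
  build_geometry(gap_widths = gap, gate_positions = position,
                 channel_length = length, channel_width = width, ...)
}

# a short three-gate benchmark channel used for transport cross-checks
benchmark_channel <- function() {
  build_geometry(gap_widths = c(80e-6, 60e-6, 50e-6),
                 gate_positions = c(0.6e-3, 0.9e-3, 1.2e-3),
                 channel_length = 1.9e-3, channel_width = 250e-6,
                 gate_pitch = 300e-6)
}

cached <- local({
  env <- new.env()
  function(key, expr) {
    if (!exists(key, envir = env, inherits = FALSE)) {
      assign(key, force(expr), envir = env)
    }
    get(key, envir = env, inherits = FALSE)
  }
})

bench_field <- function(V = 100) {
  f <- cached("bench_field_100",
              solve_potential(benchmark_channel(), 100, resolution = 10))
  if (V == 100) f else scale_field(f, V)
}

# finer benchmark grid for the stochastic-oracle cross-checks, where the
# discretized basin must match between formulations
bench_field16 <- function() {
  cached("bench_field16",
         solve_potential(benchmark_channel(), 100, resolution = 16))
}
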