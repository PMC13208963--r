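# Synthetic inputs with the statistical structure the analysis assumes.
#
# The raw sweep data behind the onset-voltage statistics are not printed
# in the main text, so the generators here emulate them: a hinge-shaped
# count-vs-voltage truth (flat baseline below the onset, linear rise
# above) with per-point relative Gaussian noise, uniform parameter ranges
# hitting target relative standard deviations, and exact error-function
# transition curves for the transition-analysis fitters.

#' Generate a synthetic voltage-sweep dataset
#'
#' Truth model: `y_i = max(0, baseline + slope * max(0, V_i - onset))`,
#' perturbed by Gaussian noise with standard deviation
#' `noise_level * y_i` and clipped at zero (counts cannot be negative).
#' Defaults emulate the spherical-isolate anchor dataset: onset 680.39 V,
#' a grid spanning onset +- 200 V in 4 V increments (dense enough to keep
#' the intercept estimator in its linear-response regime at the highest
#' noise level), and a slope giving a maximum response of about 200
#' counts.
#'
#' @param onset_voltage true onset (V).
#' @param slope response rise per volt above onset.
#' @param voltage_grid sweep voltages (V); increments of 1-10 V.
#' @param noise_level relative noise fraction (0 = noise-free).
#' @param baseline response below onset.
#' @param seed integer seed.
#' @return a [sweep_dataset()].
#' @examples
#' d <- gen_sweep(noise_level = 0)
#' fit_sweep(d)$onset_voltage   # 680.39
#' @export
gen_sweep <- function(onset_voltage = 680.39, slope = 1.0,
                      voltage_grid = seq(480, 880, by = 4),
                      noise_level = 0, baseline = 0, seed = 1L) {
  if (length(voltage_grid) < 3 || any(diff(voltage_grid) <= 0)) {
    stop("voltage_grid must be strictly increasing with >= 3 points")
  }
  inc <- diff(voltage_grid)
  if (any(inc < 1 - 1e-9) || any(inc > 10 + 1e-9)) {
    stop("voltage increments must lie between 1 and 10 V")
  }
  if (onset_voltage <= min(voltage_grid) || onset_voltage >= max(voltage_grid)) {
    stop("onset must lie inside the voltage grid span")
  }
  if (slope <= 0) stop("slope must be positive")
  if (noise_level < 0) stop("noise_level must be non-negative")
  y <- pmax(0, baseline + slope * pmax(0, voltage_grid - onset_voltage))
  if (noise_level > 0) {
    set.seed(seed)
    y <- pmax(0, y + stats::rnorm(length(y), 0, noise_level * y))
  }
  sweep_dataset(voltage_grid, y, taxon = "synthetic")
}

#' Uniform parameter ranges achieving target relative standard deviations
#'
#' A uniform distribution on `nominal +- h` has standard deviation
#' `h / sqrt(3)`, so the half-width achieving a relative standard
#' deviation `rsd` is `h = sqrt(3) * rsd * nominal`. Default targets:
#' applied voltage under 1% RSD, mobility, resistance and charge up to
#' 30% RSD, density 20%.
#'
#' @param nominal named vector of nominal values for `n`, `mu_ek`, `r`,
#'   `q`, `v`.
#' @param rsd named vector of target RSDs (fractions in \[0, 0.5\]).
#' @return list with `parameter_ranges` (for [mc_config()]) and the
#'   targets.
#' @export
gen_parameter_ranges <- function(nominal = c(n = 1e13, mu_ek = 4e-9,
                                             r = 3e9, q = 1.4e-5, v = 680),
                                 rsd = c(n = 0.20, mu_ek = 0.30,
                                         r = 0.30, q = 0.30, v = 0.01)) {
  pars <- c("n", "mu_ek", "r", "q", "v")
  if (!all(pars %in% names(nominal)) || !all(pars %in% names(rsd))) {
    stop("nominal and rsd must name all of: ", paste(pars, collapse = ", "))
  }
  if (any(rsd < 0 | rsd > 0.5)) stop("RSD targets must lie in [0, 0.5]")
  ranges <- lapply(pars, function(p) {
    h <- sqrt(3) * rsd[[p]] * nominal[[p]]
    c(nominal[[p]] - h, nominal[[p]] + h)
  })
  names(ranges) <- pars
  list(parameter_ranges = ranges, nominal = nominal[pars], rsd = rsd[pars])
}

#' Generate an exact error-function transition curve
#'
#' `percent = 100 * (1 - Phi((x - center)/sigma))`: the noise-free shape
#' assumed by [fit_erf()] and [derivative_peak()].
#'
#' @param center transition centre.
#' @param sigma transition scale, positive.
#' @param grid sweep values (default `center +- 4 sigma`, 41 points).
#' @param noise_sd additive Gaussian noise on the percentages (percentage
#'   points); clipped to \[0, 100\].
#' @param seed integer seed used when `noise_sd > 0`.
#' @return a [transition_curve()].
#' @export
gen_transition_curve <- function(center, sigma, grid = NULL, noise_sd = 0,
                                 seed = 1L) {
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(grid)) {
    grid <- seq(center - 4 * sigma, center + 4 * sigma, length.out = 41)
  }
  p <- 100 * (1 - stats::pnorm((grid - center) / sigma))
  if (noise_sd > 0) {
    set.seed(seed)
    p <- pmin(100, pmax(0, p + stats::rnorm(length(p), 0, noise_sd)))
  }
  transition_curve(grid, p, variable = "voltage")
}
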