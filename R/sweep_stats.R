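# Voltage-sweep onset statistics.
#
# The voltage-sweep protocol counts captured particles (or integrates their
# fluorescence) at stepped applied voltages; above the capture onset the
# response rises linearly with voltage, and the onset voltage is estimated
# as the baseline intercept of an ordinary least-squares fit to the rising
# limb, (y_baseline - b)/a for y = a x + b.
#
# The expected capture count follows a rate model: N particles arriving at
# the constriction in time t through a channel of width w and height h is
# N = n v t w h with drift v = mu_EK E_ave; expressing the average field
# through the channel resistance and current gives the equivalent forms
# N = n mu_EK (R i / L) t w h = n mu_EK R Q w h / L with charge Q = i t.

#' Construct a voltage-sweep dataset
#'
#' @param voltages applied voltages (V), strictly increasing, >= 3 values.
#' @param responses captured count or fluorescence intensity, non-negative.
#' @param taxon,device optional metadata labels.
#' @return an object of class `sweep_dataset`.
#' @export
sweep_dataset <- function(voltages, responses, taxon = NA_character_,
                          device = NA_character_) {
  if (length(voltages) < 3) stop("at least 3 sweep points are required")
  if (length(voltages) != length(responses)) {
    stop("voltages and responses must have equal length")
  }
  if (any(diff(voltages) <= 0)) stop("voltages must be strictly increasing")
  if (any(responses < 0)) stop("responses must be non-negative")
  structure(list(voltages = as.numeric(voltages),
                 responses = as.numeric(responses),
                 taxon = taxon, device = device),
            class = "sweep_dataset")
}

#' Parameters of the capture-count rate model
#'
#' @param n particle density (m-3).
#' @param mu_ek electrokinetic mobility (m2 V-1 s-1).
#' @param r_ave channel resistance (ohm).
#' @param q_charge charge passed through the channel in the counting
#'   interval (C).
#' @param i_ave average current (A); defaults to `q_charge / t`.
#' @param t counting interval (s).
#' @param w,h,L channel width, height, length (m).
#' @param e_ave average field (V/m); defaults to `r_ave * i_ave / L`.
#' @param chi empirical correction factor for the slope-error model.
#' @param relative_sigmas named numeric vector of relative standard
#'   deviations for `n`, `mu_ek`, `r`, `q`.
#' @return an object of class `rate_model_params`.
#' @export
rate_model_params <- function(n = 1e13, mu_ek = 4e-9, r_ave = 3e9,
                              q_charge = 1.4e-5, t = 60,
                              i_ave = q_charge / t,
                              w = 300e-6, h = 20e-6, L = 0.018,
                              e_ave = r_ave * i_ave / L,
                              chi = 1,
                              relative_sigmas = c(n = 0, mu_ek = 0,
                                                  r = 0, q = 0)) {
  vals <- c(n = n, mu_ek = mu_ek, r_ave = r_ave, q_charge = q_charge,
            i_ave = i_ave, t = t, w = w, h = h, L = L, e_ave = e_ave,
            chi = chi)
  if (any(vals <= 0)) {
    stop("non-positive rate-model parameter: ",
         paste(names(vals)[vals <= 0], collapse = ", "))
  }
  need <- c("n", "mu_ek", "r", "q")
  if (!all(need %in% names(relative_sigmas))) {
    stop("relative_sigmas must name all of: ", paste(need, collapse = ", "))
  }
  if (any(relative_sigmas < 0)) stop("relative sigmas must be non-negative")
  structure(list(n = n, mu_ek = mu_ek, r_ave = r_ave, q_charge = q_charge,
                 i_ave = i_ave, t = t, w = w, h = h, L = L, e_ave = e_ave,
                 chi = chi,
                 relative_sigmas = relative_sigmas[need]),
            class = "rate_model_params")
}

#' Expected capture count from the rate model
#'
#' Evaluates the charge form `N = n mu_EK R Q w h / L` (default), the
#' kinematic form `N = n v t w h` with `v = mu_EK E_ave`, or the current
#' form `N = n mu_EK (R i / L) t w h`. The three routes agree identically
#' when `Q = i t` and `E_ave = R i / L`.
#'
#' @param params a [rate_model_params()] object.
#' @param route `"charge"`, `"kinematic"` or `"current"`.
#' @return expected count (dimensionless).
#' @examples
#' p <- rate_model_params(n = 1, mu_ek = 1, r_ave = 1, q_charge = 1,
#'                        t = 1, w = 1, h = 1, L = 1)
#' predict_count(p)   # 1
#' @export
predict_count <- function(params, route = c("charge", "kinematic", "current")) {
  route <- match.arg(route)
  with(params, switch(route,
    charge = n * mu_ek * r_ave * q_charge * w * h / L,
    kinematic = n * (mu_ek * e_ave) * t * w * h,
    current = n * mu_ek * (r_ave * i_ave / L) * t * w * h
  ))
}

#' Propagated standard deviation of the capture count
#'
#' First-order error propagation through the charge form of the rate model
#' with the channel dimensions held fixed:
#' `sigma_N = N sqrt((s_n/n)^2 + (s_mu/mu)^2 + (s_R/R)^2 + (s_Q/Q)^2)`.
#'
#' @param params a [rate_model_params()] object carrying `relative_sigmas`.
#' @param N count to scale; defaults to [predict_count()] of `params`.
#' @return `sigma_N` on the count scale.
#' @export
propagate_sigma_n <- function(params, N = predict_count(params)) {
  rs <- params$relative_sigmas
  if (any(rs < 0)) stop("negative relative sigma")
  N * sqrt(sum(rs^2))
}

#' Standard error of the slope of a linear regression
#'
#' The textbook estimator
#' `s = sqrt( (1/(m-2)) * sum((y - yhat)^2) / sum((x - xbar)^2) )`
#' computed from a sweep dataset and its fitted line.
#'
#' @param dataset a [sweep_dataset()].
#' @param fit optionally a [fit_sweep()] result; refitted otherwise.
#' @return the slope standard error.
#' @export
slope_stderr_regression <- function(dataset, fit = NULL) {
  x <- dataset$voltages
  y <- dataset$responses
  m <- length(x)
  if (m < 3) stop("at least 3 points are required")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop("zero variance in x: slope error undefined")
  if (is.null(fit)) {
    a <- sum((x - mean(x)) * (y - mean(y))) / sxx
    b <- mean(y) - a * mean(x)
  } else {
    a <- fit$slope; b <- fit$intercept
  }
  rss <- sum((y - (a * x + b))^2)
  sqrt(rss / (m - 2) / sxx)
}

#' Model-based slope error of the voltage-sweep regression
#'
#' Combines the regression slope-error formula with the propagated count
#' uncertainty, identifying the residual sum of squares with the propagated
#' `sigma_N`:
#' `s = chi sqrt( (1/(m-2)) N (sum of squared relative sigmas) / Sxx )`
#' (`mode = "literal"`, the printed form). Because equating a sum of
#' squared residuals with a standard deviation is dimensionally irregular,
#' `mode = "squared"` substitutes `sigma_N^2` instead:
#' `s = chi sqrt( (1/(m-2)) N^2 (sum of squared relative sigmas) / Sxx )`.
#' Neither variant is endorsed; the literal form is the default.
#'
#' @param params a [rate_model_params()] object (`chi`, `relative_sigmas`).
#' @param N expected count; defaults to [predict_count()].
#' @param sum_sq_x `Sxx = sum((x - xbar)^2)` of the sweep voltages.
#' @param n_points number of sweep points, > 2.
#' @param mode `"literal"` or `"squared"`.
#' @return the model slope error `s`.
#' @export
slope_stderr_model <- function(params, N = predict_count(params), sum_sq_x,
                               n_points, mode = c("literal", "squared")) {
  mode <- match.arg(mode)
  if (n_points <= 2) stop("n_points must exceed 2")
  if (sum_sq_x <= 0) stop("sum_sq_x must be positive")
  if (N < 0) stop("N must be non-negative")
  ss <- sum(params$relative_sigmas^2)
  core <- switch(mode, literal = N * ss, squared = N^2 * ss)
  params$chi * sqrt(core / (n_points - 2) / sum_sq_x)
}

#' Fit the rising limb of a voltage sweep and estimate the onset voltage
#'
#' Ordinary least squares on the sweep points in the linear above-onset
#' regime (responses above `threshold_frac` of the maximum response,
#' because the sub-onset baseline does not follow the linear rate model),
#' then `onset = (y_baseline - b) / a`.
#'
#' @param dataset a [sweep_dataset()].
#' @param y_baseline response level defining the onset (default 0, giving
#'   `onset = -b/a`).
#' @param threshold_frac inclusion threshold as a fraction of the maximum
#'   response (default 0.05).
#' @return an object of class `sweep_fit`: `slope`, `intercept`,
#'   `slope_stderr`, `onset_voltage`, `y_baseline`,
#'   `residual_sum_squares`, `n_used`, `used` (logical index).
#' @examples
#' d <- sweep_dataset(seq(500, 900, by = 10),
#'                    pmax(0, seq(500, 900, by = 10) - 680))
#' fit_sweep(d)$onset_voltage   # 680
#' @export
fit_sweep <- function(dataset, y_baseline = 0, threshold_frac = 0.05) {
  x <- dataset$voltages
  y <- dataset$responses
  use <- y > threshold_frac * max(y)
  if (sum(use) < 3) stop("fewer than 3 points above the response threshold")
  xs <- x[use]; ys <- y[use]
  sxx <- sum((xs - mean(xs))^2)
  if (sxx <= 0) stop("zero variance in fitted voltages")
  a <- sum((xs - mean(xs)) * (ys - mean(ys))) / sxx
  b <- mean(ys) - a * mean(xs)
  if (a <= 0) {
    stop("non-positive sweep slope: onset voltage undefined for a ",
         "non-capturing sweep")
  }
  rss <- sum((ys - (a * xs + b))^2)
  s <- sqrt(rss / (sum(use) - 2) / sxx)
  structure(list(slope = a, intercept = b, slope_stderr = s,
                 onset_voltage = (y_baseline - b) / a,
                 y_baseline = y_baseline,
                 residual_sum_squares = rss,
                 n_used = sum(use), used = use,
                 dataset = dataset),
            class = "sweep_fit")
}

#' @export
print.sweep_dataset <- function(x, ...) {
  cat(sprintf("voltage-sweep dataset: %d points, %.4g-%.4g V, max response %.4g\n",
              length(x$voltages), min(x$voltages), max(x$voltages),
              max(x$responses)))
  if (!is.na(x$taxon)) cat("  taxon:", x$taxon, "\n")
  invisible(x)
}

#' @export
print.sweep_fit <- function(x, ...) {
  cat(sprintf("voltage-sweep fit: y = %.4g x + %.4g (%d points)\n",
              x$slope, x$intercept, x$n_used))
  cat(sprintf("  onset voltage: %.4g V (baseline %.4g), slope stderr %.4g\n",
              x$onset_voltage, x$y_baseline, x$slope_stderr))
  invisible(x)
}

#' @export
coef.sweep_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
plot.sweep_fit <- function(x, ...) {
  d <- x$dataset
  graphics::plot(d$voltages, d$responses, pch = ifelse(x$used, 16, 1),
                 xlab = "applied voltage (V)", ylab = "response", ...)
  graphics::abline(x$intercept, x$slope, col = 2)
  graphics::abline(v = x$onset_voltage, lty = 2)
  invisible(x)
}
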