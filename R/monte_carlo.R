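# Monte Carlo propagation of experimental uncertainty.
#
# Two uncertainty channels feed the voltage-sweep onset estimate: the
# variability of the physical quantities entering the capture-rate model
# (particle density, electrokinetic mobility, channel resistance, passed
# charge; propagated into the slope-error statistic), and counting noise
# on the recorded responses (propagated into the onset-voltage
# distribution by refitting perturbed sweeps).

#' Monte Carlo configuration
#'
#' Parameter draws are uniform on the stated ranges; correlations among
#' `mu_ek`, `r` and `q` (their measurement uncertainties are linked
#' through the buffer's zeta potential and ionic strength) are imposed on
#' the ranks via a Gaussian copula, with particle density `n` and voltage
#' `v` independent. Default rank correlations: +0.5 between `mu_ek` and
#' `r`, -0.5 between `mu_ek` and `q`.
#'
#' @param iterations number of Monte Carlo draws (>= 100; default 10000).
#' @param parameter_ranges named list of `c(lo, hi)` uniform ranges for
#'   `n`, `mu_ek`, `r`, `q`, `v`.
#' @param correlation symmetric positive semi-definite rank-correlation
#'   matrix over those five parameters (default as described).
#' @param noise_levels relative noise levels for onset propagation.
#' @param seed integer seed.
#' @param y_baseline response level defining the onset.
#' @return an object of class `mc_config`.
#' @export
mc_config <- function(iterations = 10000,
                      parameter_ranges = NULL,
                      correlation = NULL,
                      noise_levels = c(0, 0.10, 0.50, 1.00),
                      seed = 1L,
                      y_baseline = 0) {
  if (iterations < 100) stop("at least 100 iterations are required")
  pars <- c("n", "mu_ek", "r", "q", "v")
  if (is.null(parameter_ranges)) {
    parameter_ranges <- gen_parameter_ranges()$parameter_ranges
  }
  if (!all(pars %in% names(parameter_ranges))) {
    stop("parameter_ranges must name all of: ", paste(pars, collapse = ", "))
  }
  parameter_ranges <- parameter_ranges[pars]
  bad <- vapply(parameter_ranges, function(r) r[2] < r[1], logical(1))
  if (any(bad)) stop("invalid range (hi < lo) for: ",
                     paste(pars[bad], collapse = ", "))
  if (is.null(correlation)) {
    correlation <- diag(5)
    dimnames(correlation) <- list(pars, pars)
    correlation["mu_ek", "r"] <- correlation["r", "mu_ek"] <- 0.5
    correlation["mu_ek", "q"] <- correlation["q", "mu_ek"] <- -0.5
  }
  if (!isSymmetric(unname(correlation)) ||
      min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-10) {
    stop("correlation matrix must be symmetric positive semi-definite")
  }
  if (any(noise_levels < 0)) stop("noise levels must be non-negative")
  structure(list(iterations = as.integer(iterations),
                 parameter_ranges = parameter_ranges,
                 correlation = correlation,
                 noise_levels = noise_levels,
                 seed = as.integer(seed),
                 y_baseline = y_baseline),
            class = "mc_config")
}

#' Draw correlated uniform parameter samples
#'
#' Multivariate sampling with uniform marginals on the configured ranges
#' and the configured rank (Spearman) correlations, via a Gaussian copula:
#' normal deviates with Pearson correlation `2 sin(pi rho_s / 6)` are
#' transformed through the normal CDF to correlated uniforms.
#'
#' @param config an [mc_config()].
#' @return `iterations x 5` matrix with columns `n`, `mu_ek`, `r`, `q`,
#'   `v`.
#' @export
sample_parameters <- function(config) {
  pars <- names(config$parameter_ranges)
  rho_s <- config$correlation
  rho_p <- 2 * sin(pi * rho_s / 6)
  diag(rho_p) <- 1
  ev <- eigen(rho_p, symmetric = TRUE)
  if (min(ev$values) < -1e-8) stop("copula correlation matrix is not PSD")
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  set.seed(config$seed)
  z <- matrix(stats::rnorm(config$iterations * length(pars)),
              config$iterations) %*% rt
  u <- stats::pnorm(z)
  out <- sapply(seq_along(pars), function(j) {
    r <- config$parameter_ranges[[j]]
    r[1] + u[, j] * (r[2] - r[1])
  })
  colnames(out) <- pars
  out
}

#' Monte Carlo distribution of the model slope-error statistic
#'
#' Draws `n`, `mu_ek`, `r`, `q` (and voltage, which enters only through
#' the fixed sweep design), evaluates the expected count through the
#' charge-form rate model for every draw, and propagates it into the
#' model slope error via [slope_stderr_model()].
#'
#' @param config an [mc_config()].
#' @param rate_params_template a [rate_model_params()] providing the fixed
#'   quantities (`w`, `h`, `L`, `chi`, `relative_sigmas`).
#' @param sum_sq_x sweep design `Sxx` (defaults to a 41-point, 10 V step
#'   design spanning 400 V).
#' @param n_points sweep design size.
#' @param mode passed to [slope_stderr_model()].
#' @return an object of class `mc_slope_error`: vector `samples`, summary
#'   statistics, and the configuration.
#' @export
run_slope_error_mc <- function(config, rate_params_template = rate_model_params(),
                               sum_sq_x = NULL, n_points = 41,
                               mode = "literal") {
  if (is.null(sum_sq_x)) {
    xs <- seq(480, 880, by = 10)
    n_points <- length(xs)
    sum_sq_x <- sum((xs - mean(xs))^2)
  }
  draws <- sample_parameters(config)
  tpl <- rate_params_template
  s <- vapply(seq_len(nrow(draws)), function(i) {
    N <- draws[i, "n"] * draws[i, "mu_ek"] * draws[i, "r"] * draws[i, "q"] *
      tpl$w * tpl$h / tpl$L
    slope_stderr_model(tpl, N = N, sum_sq_x = sum_sq_x,
                       n_points = n_points, mode = mode)
  }, numeric(1))
  structure(list(samples = s,
                 mean = mean(s), median = stats::median(s),
                 sd = stats::sd(s),
                 rsd_percent = 100 * stats::sd(s) / mean(s),
                 config = config, mode = mode),
            class = "mc_slope_error")
}

#' Monte Carlo distribution of the onset voltage under response noise
#'
#' Per iteration, every response `y_i` of the sweep is perturbed by
#' Gaussian noise with standard deviation `noise_level * y_i` (per-point
#' relative convention; `base = "mean"` uses `noise_level * mean(y)`
#' instead), negative perturbed counts are clipped to zero, the rising
#' limb is refitted and the onset recomputed.
#'
#' @param dataset a [sweep_dataset()] that fits successfully unperturbed.
#' @param noise_level relative noise level (e.g. 0.5 for 50%).
#' @param config an [mc_config()] (iterations, seed, y_baseline).
#' @param base `"point"` (default) or `"mean"` noise scaling.
#' @return an object of class `onset_distribution`: `samples`, `mean`,
#'   `sd`, `rsd_percent`, `quartiles`, `nominal_onset`, `noise_level`,
#'   `n_failed`.
#' @export
run_onset_mc <- function(dataset, noise_level, config = mc_config(),
                         base = c("point", "mean")) {
  base <- match.arg(base)
  fit0 <- fit_sweep(dataset, y_baseline = config$y_baseline)
  nominal <- fit0$onset_voltage
  set.seed(config$seed + round(1000 * noise_level))
  y <- dataset$responses
  sdv <- switch(base, point = noise_level * y,
                mean = rep(noise_level * mean(y), length(y)))
  # the fitted rising limb is selected once, from the unperturbed sweep;
  # re-selecting it per noisy replicate would bias the onset downwards
  use <- fit0$used
  xs <- dataset$voltages[use]
  xbar <- mean(xs); sxx <- sum((xs - xbar)^2)
  samples <- numeric(config$iterations)
  failed <- 0L
  for (i in seq_len(config$iterations)) {
    yi <- pmax(0, y + stats::rnorm(length(y), 0, sdv))[use]
    a <- sum((xs - xbar) * (yi - mean(yi))) / sxx
    if (a <= 0) {
      failed <- failed + 1L
      samples[i] <- NA_real_
    } else {
      b <- mean(yi) - a * xbar
      samples[i] <- (config$y_baseline - b) / a
    }
  }
  if (failed > 0.1 * config$iterations) {
    stop("fit failure rate above 10% (", failed, " of ",
         config$iterations, " iterations)")
  }
  samples <- samples[!is.na(samples)]
  structure(list(samples = samples,
                 mean = mean(samples), sd = stats::sd(samples),
                 rsd_percent = 100 * stats::sd(samples) / mean(samples),
                 quartiles = stats::quantile(samples, c(0.25, 0.5, 0.75)),
                 nominal_onset = nominal,
                 noise_level = noise_level,
                 n_failed = failed,
                 config = config),
            class = "onset_distribution")
}

#' Summary statistics of an onset-voltage distribution
#'
#' @param object an [run_onset_mc()] result (or any object with a
#'   `samples` vector).
#' @param ... unused.
#' @return list with `mean`, `sd`, `rsd_percent`, `quartiles`, Tukey
#'   `fences` (1.5 IQR) and the `outliers` beyond them.
#' @export
summary.onset_distribution <- function(object, ...) {
  s <- object$samples
  if (!length(s)) stop("empty sample vector")
  q <- stats::quantile(s, c(0.25, 0.5, 0.75))
  iqr <- q[3] - q[1]
  fences <- c(lower = unname(q[1] - 1.5 * iqr),
              upper = unname(q[3] + 1.5 * iqr))
  out <- list(mean = mean(s), sd = stats::sd(s),
              rsd_percent = 100 * stats::sd(s) / mean(s),
              quartiles = q, fences = fences,
              outliers = s[s < fences[1] | s > fences[2]],
              n = length(s),
              nominal_onset = object$nominal_onset,
              noise_level = object$noise_level)
  class(out) <- "summary.onset_distribution"
  out
}

#' @export
print.summary.onset_distribution <- function(x, ...) {
  cat(sprintf("onset-voltage distribution (noise level %.0f%%, n = %d)\n",
              100 * x$noise_level, x$n))
  cat(sprintf("  mean %.2f V, sd %.2f V (RSD %.2f%%), nominal %.2f V\n",
              x$mean, x$sd, x$rsd_percent, x$nominal_onset))
  cat(sprintf("  quartiles %.2f / %.2f / %.2f V, %d outliers beyond 1.5 IQR\n",
              x$quartiles[1], x$quartiles[2], x$quartiles[3],
              length(x$outliers)))
  invisible(x)
}

#' @export
print.onset_distribution <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' @export
print.mc_slope_error <- function(x, ...) {
  cat(sprintf("slope-error Monte Carlo (%d iterations, %s mode)\n",
              length(x$samples), x$mode))
  cat(sprintf("  mean %.4g, median %.4g, sd %.4g (RSD %.2f%%)\n",
              x$mean, x$median, x$sd, x$rsd_percent))
  invisible(x)
}

#' @export
print.mc_config <- function(x, ...) {
  cat(sprintf("Monte Carlo configuration: %d iterations, seed %d\n",
              x$iterations, x$seed))
  for (p in names(x$parameter_ranges)) {
    r <- x$parameter_ranges[[p]]
    cat(sprintf("  %-6s uniform [%.4g, %.4g]\n", p, r[1], r[2]))
  }
  cat("  noise levels:", paste(100 * x$noise_levels, collapse = "/"), "%\n")
  invisible(x)
}

#' Onset-distribution comparison across noise levels
#'
#' Convenience wrapper running [run_onset_mc()] at each configured noise
#' level of `config`.
#'
#' @param dataset a [sweep_dataset()].
#' @param config an [mc_config()].
#' @param base noise convention, see [run_onset_mc()].
#' @return list of `onset_distribution` objects, one per noise level.
#' @export
onset_noise_study <- function(dataset, config = mc_config(),
                              base = "point") {
  out <- lapply(config$noise_levels, function(f) {
    run_onset_mc(dataset, f, config, base = base)
  })
  names(out) <- paste0("noise_", 100 * config$noise_levels, "pct")
  out
}
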