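# Transition-zone analysis: sweep voltage or DEP mobility, extract the
# partial-capture window, fit an error function and convert its derivative
# into Gaussian variance metrics. The width of the partial-capture window
# for a mathematically monodisperse population is the channel-imposed
# contribution to the separation variance.

#' Sweep applied voltage or DEP mobility and record percent passed
#'
#' Runs one stationary transport solve per grid point on a shared reference
#' field solution (rescaled per voltage; the field solve is done once) and
#' assembles the percent-passed transition curve. The sweep grid defaults
#' to a window around the predicted centreline-capture onset and is refined
#' near the 5% and 95% capture edges by bisection.
#'
#' @param geometry a [build_geometry()] object (or preset name).
#' @param params a [physical_params()] object; `mu_dep` must be negative
#'   for a capture transition to exist.
#' @param variable `"voltage"` or `"mu_dep"`.
#' @param grid sweep values (V, or m4 V-2 s-1 magnitudes are taken from
#'   their absolute values); default: 12 points bracketing the transition.
#' @param fixed_value the fixed applied voltage (for a `mu_dep` sweep) or
#'   fixed `mu_dep` is taken from `params`. For a voltage sweep this is
#'   ignored.
#' @param resolution grid resolution for the field solve.
#' @param readout_gate capture readout gate (default: third-to-last).
#' @param refine logical: bisect the 5%/95% capture edges until their
#'   bracket is below `precision`.
#' @param precision target edge resolution; default 1/50 of the initial
#'   sweep span.
#' @param max_extra maximum number of refinement solves.
#' @param field optional precomputed [solve_potential()] reference
#'   solution; by default the channel is solved on a window spanning the
#'   gates with gap width at most `window_gap_factor` times the minimum
#'   gap (the wide upstream gates contribute negligible beam shaping at
#'   transition voltages).
#' @param window_gap_factor see `field`.
#' @return An object of class `transition_curve`: data frame fields
#'   `x_values`, `percent_passed`, the sweep `variable`, and metadata.
#' @export
sweep_capture <- function(geometry, params = physical_params(),
                          variable = c("voltage", "mu_dep"), grid = NULL,
                          fixed_value = NULL, resolution = 10,
                          readout_gate = NULL, refine = TRUE,
                          precision = NULL, max_extra = 10, field = NULL,
                          window_gap_factor = 6) {
  variable <- match.arg(variable)
  if (is.character(geometry)) geometry <- build_geometry(geometry)
  if (params$mu_dep >= 0) {
    stop("no capture transition: mu_dep must be negative (repulsive DEP)")
  }
  if (is.null(field)) {
    keep <- which(geometry$gates$gap <= window_gap_factor * geometry$min_gap)
    window <- if (length(keep) < geometry$n_gates) range(keep) else NULL
    field <- solve_potential(geometry, 100, params = params,
                             resolution = resolution, window = window)
  }
  v_onset <- predict_onset_voltage(field, params$mu_ek, params$mu_dep)

  eval_pct <- function(x) {
    if (variable == "voltage") {
      solve_transport(scale_field(field, x), params,
                      readout_gate = readout_gate)$percent_passed
    } else {
      p2 <- params
      p2$mu_dep <- -abs(x)
      V <- if (is.null(fixed_value)) field$applied_voltage else fixed_value
      solve_transport(scale_field(field, V), p2,
                      readout_gate = readout_gate)$percent_passed
    }
  }

  if (is.null(grid)) {
    if (variable == "voltage") {
      grid <- v_onset * seq(0.3, 1.05, length.out = 14)
    } else {
      V <- if (is.null(fixed_value)) field$applied_voltage else fixed_value
      mu_c <- params$mu_ek / (max(ekmr_profile(field)$ekmr_Vpm2) *
                                V / field$applied_voltage)
      grid <- mu_c * seq(0.45, 1.1, length.out = 12)
    }
  }
  grid <- sort(abs(grid))
  if (length(grid) < 8) stop("at least 8 sweep points are required")
  pct <- vapply(grid, eval_pct, numeric(1))

  cap <- max(pct) - pct   # capture relative to the open plateau
  amp <- max(pct) - min(pct)
  if (amp < 20 || min(pct) > 0.1 * max(pct)) {
    stop("transition not bracketed by the sweep grid (percent passed spans ",
         signif(min(pct), 3), "-", signif(max(pct), 3),
         "); widen the grid or check mu_dep")
  }
  if (is.null(precision)) precision <- (max(grid) - min(grid)) / 50

  # bisection refinement of the 5% and 95% capture edges
  if (refine) {
    extra <- 0
    for (lev in c(0.05, 0.95) * amp) {
      repeat {
        cap <- max(pct) - pct
        ix <- which(diff(cap >= lev) != 0)
        if (!length(ix)) break
        i <- ix[1]
        if (grid[i + 1] - grid[i] <= precision || extra >= max_extra) break
        xm <- (grid[i] + grid[i + 1]) / 2
        pm <- eval_pct(xm)
        pos <- findInterval(xm, grid)
        grid <- append(grid, xm, after = pos)
        pct <- append(pct, pm, after = pos)
        extra <- extra + 1
      }
    }
  }

  structure(list(
    x_values = grid, percent_passed = pct, variable = variable,
    geometry = geometry$name,
    fixed_value = if (variable == "mu_dep") {
      if (is.null(fixed_value)) field$applied_voltage else fixed_value
    } else params$mu_dep,
    params = params, predicted_onset = v_onset
  ), class = "transition_curve")
}

#' Construct a transition curve from raw values
#'
#' @param x_values sweep values, strictly monotone.
#' @param percent_passed percentages in \[0, 100\].
#' @param variable `"voltage"` or `"mu_dep"`.
#' @return a `transition_curve`.
#' @export
transition_curve <- function(x_values, percent_passed,
                             variable = c("voltage", "mu_dep")) {
  variable <- match.arg(variable)
  stopifnot(length(x_values) == length(percent_passed))
  if (any(diff(x_values) <= 0)) stop("x_values must be strictly increasing")
  if (any(percent_passed < -1e-9 | percent_passed > 100 + 1e-9)) {
    stop("percent_passed must lie in [0, 100]")
  }
  structure(list(x_values = x_values, percent_passed = percent_passed,
                 variable = variable), class = "transition_curve")
}

#' Partial-capture range of a transition curve
#'
#' Locates the sweep values at which capture reaches `lo` and `hi` percent
#' of the transition amplitude (default 5% and 95%) by linear interpolation
#' between bracketing grid points, and returns their separation
#' `delta = x95 - x5`, the partial-capture window. Curves of either
#' orientation (passing fraction decreasing or increasing) are handled.
#'
#' @param curve a `transition_curve`.
#' @param lo,hi capture levels in percent of the transition amplitude.
#' @param smooth logical: apply isotonic (pool-adjacent-violators)
#'   regression to the capture fraction before locating the crossings.
#'   Physically the capture fraction is monotone in the swept variable;
#'   solver-level wobble of a few percentage points would otherwise create
#'   spurious early crossings.
#' @return list with `x5`, `x95`, `delta`.
#' @export
partial_range <- function(curve, lo = 5, hi = 95, smooth = TRUE) {
  stopifnot(lo < hi)
  x <- curve$x_values
  p <- curve$percent_passed
  # capture fraction oriented so it increases along x
  capt <- max(p) - p
  if (capt[1] > capt[length(capt)]) {
    capt <- rev(capt); x <- rev(x) * -1  # mirror for interpolation, unmirror later
    mirrored <- TRUE
  } else mirrored <- FALSE
  if (smooth && length(capt) >= 5) capt <- stats::runmed(capt, 3)
  if (smooth) capt <- stats::isoreg(seq_along(capt), capt)$yf
  amp <- max(capt) - min(capt)
  if (amp <= 0) stop("flat curve: no transition to locate")
  cross <- function(level) {
    ix <- which(capt[-1] >= level & capt[-length(capt)] < level)
    if (!length(ix)) {
      if (capt[1] >= level) return(x[1])
      stop("capture level ", signif(level, 3), "% not crossed by the curve")
    }
    i <- ix[1]
    x[i] + (level - capt[i]) * (x[i + 1] - x[i]) / (capt[i + 1] - capt[i])
  }
  x5 <- cross(min(capt) + lo / 100 * amp)
  x95 <- cross(min(capt) + hi / 100 * amp)
  if (mirrored) {
    tmp <- -x5; x5 <- -x95; x95 <- tmp
  }
  list(x5 = min(x5, x95), x95 = max(x5, x95), delta = abs(x95 - x5))
}

#' Error-function fit of a transition curve
#'
#' Fits `percent = A * (1 - Phi((x - center)/sigma)) + B` by nonlinear
#' least squares (Levenberg-Marquardt), the model form implied by a
#' Gaussian distribution of capture thresholds.
#'
#' @param curve a `transition_curve`.
#' @return list with `center`, `sigma`, `amplitude`, `baseline`, and the
#'   `fit` object.
#' @export
fit_erf <- function(curve) {
  x <- curve$x_values
  p <- curve$percent_passed
  if (length(x) < 6) stop("at least 6 points are required for the erf fit")
  pr <- partial_range(curve)
  increasing <- stats::cor(x, p) > 0
  A0 <- max(p) - min(p)
  if (A0 <= 0) stop("degenerate flat curve")
  s0 <- max(pr$delta / 3.2897, diff(range(x)) / 100)
  c0 <- (pr$x5 + pr$x95) / 2
  sgn <- if (increasing) -1 else 1
  df <- data.frame(x = x, p = p)
  fit <- minpack.lm::nlsLM(
    p ~ A * (1 - stats::pnorm(sgn * (x - center) / sigma)) + B,
    data = df,
    start = list(A = A0, B = min(p), center = c0, sigma = s0),
    lower = c(A = 0, B = -10, center = min(x) - diff(range(x)),
              sigma = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  list(center = unname(cf["center"]), sigma = unname(cf["sigma"]),
       amplitude = unname(cf["A"]), baseline = unname(cf["B"]),
       increasing = increasing, fit = fit)
}

#' Gaussian summary of the transition derivative
#'
#' The derivative of an error-function transition is a Gaussian whose
#' standard deviation quantifies the channel-imposed dispersion. Returns
#' `sigma`, `variance = sigma^2` and `fwhm = 2.3548 sigma`, plus the
#' integral of the fitted derivative (which recovers the transition
#' amplitude) and, optionally, the raw finite-difference derivative.
#'
#' @param curve a `transition_curve`.
#' @param method `"erf"` (default, from the fitted error function) or
#'   `"finite_diff"` for the raw numerical derivative.
#' @return list with `sigma`, `variance`, `fwhm`, `center`, `amplitude`,
#'   `derivative_area`, and for `"finite_diff"` a data frame `derivative`.
#' @export
derivative_peak <- function(curve, method = c("erf", "finite_diff")) {
  method <- match.arg(method)
  ft <- fit_erf(curve)
  out <- list(sigma = ft$sigma, variance = ft$sigma^2,
              fwhm = 2 * sqrt(2 * log(2)) * ft$sigma,
              center = ft$center, amplitude = ft$amplitude)
  # area under |d/dx| of the fitted curve over a wide window
  xs <- seq(ft$center - 6 * ft$sigma, ft$center + 6 * ft$sigma,
            length.out = 2001)
  dens <- ft$amplitude * stats::dnorm((xs - ft$center) / ft$sigma) / ft$sigma
  out$derivative_area <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(xs))
  if (method == "finite_diff") {
    x <- curve$x_values; p <- curve$percent_passed
    xm <- (x[-1] + x[-length(x)]) / 2
    d <- abs(diff(p) / diff(x))
    out$derivative <- data.frame(x = xm, density = d)
    out$peak_x <- xm[which.max(d)]
  }
  out
}

#' Resolvability of two populations under the 4-sigma criterion
#'
#' Two Gaussian populations separated by `delta_x` with common standard
#' deviation `sigma` are considered resolved when `delta_x >= 4 sigma`; the
#' per-population overlap beyond the midpoint is `Phi(-delta_x / (2 sigma))`
#' (2.28% at exactly 4 sigma).
#'
#' @param delta_x separation along the measurement axis (same units as
#'   `sigma`), non-negative.
#' @param sigma common population standard deviation, positive.
#' @return list with `resolved` (logical), `overlap_fraction`, and the
#'   `separation_sigmas` ratio.
#' @examples
#' resolvability(96, 24)   # resolved at exactly 4 sigma, overlap 2.28%
#' @export
resolvability <- function(delta_x, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  if (delta_x < 0) stop("delta_x must be non-negative")
  list(resolved = delta_x >= 4 * sigma,
       overlap_fraction = stats::pnorm(-delta_x / (2 * sigma)),
       separation_sigmas = delta_x / sigma)
}

#' Map an applied-voltage interval to an EKMr interval
#'
#' The peak centreline mobility-ratio `|grad E^2| / E` scales linearly with
#' the applied voltage, so a voltage window maps to an EKMr window through
#' one reference field solution.
#'
#' @param field a [solve_potential()] solution.
#' @param v_lo,v_hi voltage interval bounds (V), `v_lo < v_hi`.
#' @return list with `ekmr_lo`, `ekmr_hi` (V/m2) and the reference slope
#'   `ekmr_per_volt`.
#' @export
voltage_range_to_ekmr_range <- function(field, v_lo, v_hi) {
  if (v_lo >= v_hi) stop("empty voltage interval: v_lo must be < v_hi")
  if (v_lo <= 0) stop("voltages must be positive")
  k <- max(ekmr_profile(field)$ekmr_Vpm2) / field$applied_voltage
  list(ekmr_lo = k * v_lo, ekmr_hi = k * v_hi, ekmr_per_volt = k)
}

#' @export
print.transition_curve <- function(x, ...) {
  cat(sprintf("g-iDEP transition curve (%s sweep, %d points)\n",
              x$variable, length(x$x_values)))
  rng <- range(x$x_values)
  cat(sprintf("  sweep range: %.4g to %.4g, percent passed %.1f to %.1f\n",
              rng[1], rng[2], min(x$percent_passed), max(x$percent_passed)))
  pr <- try(partial_range(x), silent = TRUE)
  if (!inherits(pr, "try-error")) {
    cat(sprintf("  partial-capture window: delta = %.4g (x5 = %.4g, x95 = %.4g)\n",
                pr$delta, pr$x5, pr$x95))
  }
  invisible(x)
}

#' @export
summary.transition_curve <- function(object, ...) {
  pr <- partial_range(object)
  ft <- tryCatch(derivative_peak(object), error = function(e) NULL)
  out <- list(curve = object, partial_range = pr, gaussian = ft)
  class(out) <- "summary.transition_curve"
  out
}

#' @export
print.summary.transition_curve <- function(x, ...) {
  print(x$curve)
  if (!is.null(x$gaussian)) {
    cat(sprintf("  erf fit: center %.4g, sigma %.4g, FWHM %.4g, variance %.4g\n",
                x$gaussian$center, x$gaussian$sigma, x$gaussian$fwhm,
                x$gaussian$variance))
  }
  invisible(x)
}

#' @export
plot.transition_curve <- function(x, ...) {
  graphics::plot(x$x_values, x$percent_passed, type = "b", pch = 16,
                 xlab = if (x$variable == "voltage") "applied voltage (V)"
                        else "|mu_DEP| (m4 V-2 s-1)",
                 ylab = "percent passed", ...)
  ft <- tryCatch(fit_erf(x), error = function(e) NULL)
  if (!is.null(ft)) {
    xs <- seq(min(x$x_values), max(x$x_values), length.out = 300)
    sgn <- if (ft$increasing) -1 else 1
    graphics::lines(xs, ft$amplitude *
                      (1 - stats::pnorm(sgn * (xs - ft$center) / ft$sigma)) +
                      ft$baseline, col = 2)
  }
  invisible(x)
}
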