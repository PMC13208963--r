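#' Parametric gated-channel geometries for g-iDEP devices
#'
#' A g-iDEP channel is a straight microchannel interrupted by successive
#' "gates": pairs of triangular (wedge) insulators protruding symmetrically
#' from the side walls, leaving a centred gap. Gap widths decrease from inlet
#' to outlet in sets, so the field gradient at the gates increases along the
#' channel and particles with different mobilities capture at different gates
#' (or, at one gate, at different applied voltages).
#'
#' `build_geometry()` returns a validated `gidep_geometry` object either from
#' a named preset or from explicit parameters. Two presets are provided:
#' \describe{
#'   \item{`"V2L"`}{27 gates in nine three-gate sets, minimum gap 27 um.}
#'   \item{`"V2S"`}{24 gates in eight three-gate sets, minimum gap 3 um.}
#' }
#' The published designs do not print the insulator vertex coordinates, so
#' each gate is modelled as a symmetric wedge pair parameterized by its gap
#' width and a half-angle (default 45 degrees between the insulator face and
#' the channel axis), with rounded tips; the per-set gap widths are
#' interpolated geometrically between the channel width and the stated
#' minimum gap.
#'
#' @param preset `"V2L"`, `"V2S"`, or `NULL` for a custom geometry.
#' @param gap_widths numeric vector of gap widths (m), one per gate, strictly
#'   positive, smaller than `channel_width`, and non-increasing from inlet to
#'   outlet. Ignored when `preset` is given.
#' @param gate_positions axial gate-centre positions (m), strictly increasing.
#'   Defaults to a uniform pitch starting after `lead_length`.
#' @param channel_width full transverse width of the channel (m).
#' @param channel_length total channel length (m); must accommodate all gates.
#' @param channel_height out-of-plane depth (m); the model is two-dimensional,
#'   the height only scales absolute currents and counts.
#' @param half_angle wedge half-angle in degrees (angle between insulator face
#'   and channel axis).
#' @param tip_radius rounding length (m) applied to the wedge tips; fabricated
#'   insulators have finite tip radii and a sharp corner would make the field
#'   singular. Capped at one third of the local gap width.
#' @param gate_pitch centre-to-centre gate spacing (m) used when
#'   `gate_positions` is not supplied.
#' @param lead_length straight inlet/outlet lead length (m) used when
#'   `gate_positions` is not supplied.
#' @param name label for the geometry.
#'
#' @return An object of class `gidep_geometry`: a list with the channel
#'   dimensions, a `gates` data frame (`position`, `gap`, `tip_radius`),
#'   `n_gates`, `half_angle` (radians) and `min_gap`.
#' @examples
#' g <- build_geometry("V2L")
#' g$n_gates          # 27
#' min(g$gates$gap)   # 27e-6
#' @export
build_geometry <- function(preset = NULL,
                           gap_widths = NULL,
                           gate_positions = NULL,
                           channel_width = 300e-6,
                           channel_length = NULL,
                           channel_height = 20e-6,
                           half_angle = 45,
                           tip_radius = 2e-6,
                           gate_pitch = 320e-6,
                           lead_length = NULL,
                           name = NULL) {
  if (!is.null(preset)) {
    pre <- switch(toupper(preset),
      V2L = list(n = 27L, min_gap = 27e-6, lead = 5.35e-3),
      V2S = list(n = 24L, min_gap = 3e-6, lead = 5.35e-3),
      stop("unknown geometry preset: ", preset, " (available: V2L, V2S)")
    )
    # three-gate sets: gap widths decrease geometrically from the channel
    # width to the published minimum gap across the sets; the terminal
    # three gates carry the minimum gap
    per_set <- 3L
    n_sets <- pre$n %/% per_set
    set_gaps <- channel_width * (pre$min_gap / channel_width)^(seq_len(n_sets) / n_sets)
    set_gaps[n_sets] <- pre$min_gap
    gap_widths <- rep(set_gaps, each = per_set)
    if (is.null(lead_length)) lead_length <- pre$lead
    if (is.null(name)) name <- toupper(preset)
  }
  if (is.null(gap_widths)) stop("either a preset or explicit gap_widths is required")
  n <- length(gap_widths)
  if (any(!is.finite(gap_widths)) || any(gap_widths <= 0)) {
    stop("gap widths must be strictly positive")
  }
  if (any(gap_widths >= channel_width)) {
    stop("gap widths must be smaller than the channel width")
  }
  if (any(diff(gap_widths) > 1e-12 * channel_width)) {
    stop("gap widths must be non-increasing from inlet to outlet")
  }
  if (is.null(lead_length)) lead_length <- 10 * gate_pitch
  if (is.null(gate_positions)) {
    gate_positions <- lead_length + gate_pitch * (seq_len(n) - 0.5)
  }
  if (length(gate_positions) != n) {
    stop("gate_positions and gap_widths must have equal length")
  }
  if (any(diff(gate_positions) <= 0)) stop("gate positions must be strictly increasing")
  theta <- half_angle * pi / 180
  if (theta <= 0 || theta >= pi / 2) stop("half_angle must lie in (0, 90) degrees")
  if (tip_radius < 0) stop("tip_radius must be non-negative")
  r_tip <- pmin(tip_radius, gap_widths / 3)
  # wedge axial half-footprints; gates must not overlap
  foot <- (channel_width - gap_widths + 2 * r_tip) / 2 / tan(theta)
  if (n > 1 && any(gate_positions[-1] - foot[-1] < gate_positions[-n] + foot[-n])) {
    stop("wedge footprints overlap; increase gate spacing or half_angle")
  }
  if (is.null(channel_length)) {
    if (n == 0L) stop("channel_length is required for a gate-free channel")
    channel_length <- gate_positions[n] + foot[n] + lead_length
  }
  if (n > 0L && (gate_positions[1] - foot[1] <= 0 ||
                 gate_positions[n] + foot[n] >= channel_length)) {
    stop("gates do not fit inside the channel length")
  }
  structure(list(
    name = if (is.null(name)) "custom" else name,
    channel_length = channel_length,
    channel_width = channel_width,
    channel_height = channel_height,
    half_angle = theta,
    gates = data.frame(position = gate_positions, gap = gap_widths,
                       tip_radius = r_tip),
    n_gates = n,
    min_gap = if (n > 0L) min(gap_widths) else channel_width
  ), class = "gidep_geometry")
}

#' Local fluid half-width of a gated channel
#'
#' Half-width of the fluid domain at axial positions `x`: `channel_width/2`
#' in plain segments, pinched to `gap/2` at each gate centre by the wedge
#' faces (slope `tan(half_angle)`), with the tip rounded over the gate's
#' `tip_radius`.
#'
#' @param geometry a `gidep_geometry`.
#' @param x numeric vector of axial positions (m).
#' @return numeric vector of half-widths (m).
#' @export
channel_halfwidth <- function(geometry, x) {
  w <- rep(geometry$channel_width / 2, length(x))
  tt <- tan(geometry$half_angle)
  for (k in seq_len(geometry$n_gates)) {
    r <- geometry$gates$tip_radius[k]
    dxk <- x - geometry$gates$position[k]
    wk <- geometry$gates$gap[k] / 2 - r + sqrt(r^2 + (dxk * tt)^2)
    w <- pmin(w, wk)
  }
  w
}

# Axial extent (half-footprint) of gate k's wedge pair.
gate_footprint <- function(geometry, k = seq_len(geometry$n_gates)) {
  (geometry$channel_width - geometry$gates$gap[k] + 2 * geometry$gates$tip_radius[k]) /
    2 / tan(geometry$half_angle)
}

#' Lumped axial resistance integral of the channel
#'
#' Computes the one-dimensional resistance integral `int dx / (2 w(x))`
#' (dimensionless; divide by conductivity times depth for ohms) between two
#' axial positions, using the exact piecewise-log primitive of the wedge
#' profile. Used to apportion the applied voltage onto solver windows.
#'
#' @param geometry a `gidep_geometry`.
#' @param from,to axial positions (m); default the full channel.
#' @return numeric scalar, the dimensionless resistance integral.
#' @export
channel_resistance <- function(geometry, from = 0, to = geometry$channel_length) {
  stopifnot(to >= from, from >= -1e-12, to <= geometry$channel_length + 1e-12)
  tt <- tan(geometry$half_angle)
  W2 <- geometry$channel_width / 2
  # breakpoints: segment edges where the active wedge changes
  bp <- sort(unique(c(from, to, unlist(lapply(seq_len(geometry$n_gates), function(k) {
    p <- geometry$gates$position[k]
    f <- gate_footprint(geometry, k)
    c(p - f, p, p + f)
  })))))
  bp <- bp[bp >= from & bp <= to]
  bp <- sort(unique(c(from, bp, to)))
  total <- 0
  for (i in seq_len(length(bp) - 1L)) {
    a <- bp[i]; b <- bp[i + 1L]
    if (b - a <= 0) next
    wm <- channel_halfwidth(geometry, (a + b) / 2)
    if (wm >= W2 - 1e-15) {           # plain segment, exact
      total <- total + (b - a) / (2 * W2)
    } else {                          # wedge flank: composite Simpson on 1/(2w)
      m <- 200L
      xs <- seq(a, b, length.out = m + 1L)
      fx <- 1 / (2 * channel_halfwidth(geometry, xs))
      wgt <- c(1, rep(c(4, 2), length.out = m - 1L), 1)
      total <- total + (b - a) / (3 * m) * sum(wgt * fx)
    }
  }
  total
}

#' Physical parameter set for field, flow and transport models
#'
#' Bundles buffer and particle properties. Defaults are the buffer used for
#' bacterial g-iDEP modelling: conductivity 40 uS/cm, relative permittivity
#' 80, density 1000 kg/m3, viscosity 1 mPa s. `mu_ek` is the combined
#' electrokinetic (electroosmotic + electrophoretic) mobility; `mu_dep` the
#' dielectrophoretic mobility, negative for the bacteria modelled here
#' (repelled from field maxima). The default diffusion coefficient is the
#' deliberately inflated value used in the capture model (see the methods
#' vignette); physical diffusivities of micron-sized cells are ~3 orders of
#' magnitude smaller.
#'
#' @param conductivity buffer conductivity (S/m).
#' @param relative_permittivity relative permittivity (dimensionless, >= 1).
#' @param viscosity dynamic viscosity (Pa s).
#' @param density fluid density (kg/m3).
#' @param mu_ek electrokinetic mobility (m2 V-1 s-1).
#' @param mu_dep dielectrophoretic mobility (m4 V-2 s-1), signed.
#' @param diffusion_coefficient dispersion coefficient (m2/s).
#' @return An object of class `gidep_params` (a validated list).
#' @export
physical_params <- function(conductivity = 40e-4 / 10,   # 40 uS/cm in S/m
                            relative_permittivity = 80,
                            viscosity = 1e-3,
                            density = 1000,
                            mu_ek = 4.0e-9,
                            mu_dep = -4e-19,
                            diffusion_coefficient = 2.2e-10) {
  if (conductivity <= 0) stop("conductivity must be positive")
  if (relative_permittivity < 1) stop("relative_permittivity must be >= 1")
  if (viscosity <= 0) stop("viscosity must be positive")
  if (density <= 0) stop("density must be positive")
  if (diffusion_coefficient <= 0) stop("diffusion_coefficient must be positive")
  structure(list(
    conductivity = conductivity,
    relative_permittivity = relative_permittivity,
    viscosity = viscosity,
    density = density,
    mu_ek = mu_ek,
    mu_dep = mu_dep,
    diffusion_coefficient = diffusion_coefficient
  ), class = "gidep_params")
}

#' Reference study conditions for the capture-transition simulations
#'
#' Physical parameters of the monodisperse reference population used to
#' probe the channel-imposed transition of each device, anchored to the
#' published operating points: both devices are driven so that the
#' reference particle (`mu_dep = -4e-19` m4 V-2 s-1) transitions at the
#' voltage where the two designs produce equal peak field gradients at
#' their gaps (1050 V for the large-gap design, whose matched counterpart
#' on the small-gap design is about 45 V). That fixes the electrokinetic
#' mobility at `mu_ek = EKMr_peak(V_op) * |mu_dep|`: 6.1e-9 m2/Vs (V2L)
#' and 1.8e-8 m2/Vs (V2S). Diffusion coefficients are the deliberately
#' inflated modelling values paired with each device (2.2e-10 and
#' 4.4e-11 m2/s).
#'
#' @param device `"V2L"` or `"V2S"`.
#' @param mu_dep DEP mobility override (m4 V-2 s-1).
#' @return a [physical_params()] object.
#' @export
study_conditions <- function(device = c("V2L", "V2S"), mu_dep = -4e-19) {
  device <- match.arg(toupper(device), c("V2L", "V2S"))
  switch(device,
    V2L = physical_params(mu_ek = 6.1e-9, mu_dep = mu_dep,
                          diffusion_coefficient = 2.2e-10),
    V2S = physical_params(mu_ek = 1.8e-8, mu_dep = mu_dep,
                          diffusion_coefficient = 4.4e-11)
  )
}

#' @export
print.gidep_geometry <- function(x, ...) {
  cat(sprintf("g-iDEP channel geometry \"%s\"\n", x$name))
  cat(sprintf("  channel: %.3g mm x %.3g um (depth %.3g um)\n",
              1e3 * x$channel_length, 1e6 * x$channel_width, 1e6 * x$channel_height))
  sets <- rle(signif(x$gates$gap, 6))
  cat(sprintf("  gates: %d (min gap %.3g um), wedge half-angle %.1f deg\n",
              x$n_gates, 1e6 * x$min_gap, 180 / pi * x$half_angle))
  cat(sprintf("  gate sets: %s\n",
              paste(sprintf("%d x %.3g um", sets$lengths, 1e6 * sets$values),
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.gidep_params <- function(x, ...) {
  cat("g-iDEP physical parameters\n")
  cat(sprintf("  conductivity %.3g S/m, eps_r %.3g, viscosity %.3g Pa s\n",
              x$conductivity, x$relative_permittivity, x$viscosity))
  cat(sprintf("  mu_EK %.3g m2/Vs, mu_DEP %.3g m4/V2s, D %.3g m2/s\n",
              x$mu_ek, x$mu_dep, x$diffusion_coefficient))
  invisible(x)
}
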