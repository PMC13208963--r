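# Electrokinetic mobility ratio (EKMr) and device dynamic range.
#
# At the capture onset the ratio of a particle's electrokinetic to
# dielectrophoretic mobility equals the local field ratio grad(E^2)/E at
# the capture location, so EKMr (V/m2) is the natural one-dimensional axis
# for comparing particles and devices. The accessible EKMr window of a
# device spans the spatial spread of gate-peak ratios times the usable
# voltage range.

#' Electrokinetic mobility ratio
#'
#' `ekmr = mu_ek / |mu_dep|` (V/m2). The magnitude of the (typically
#' negative) DEP mobility is used so reported ratios are positive.
#'
#' @param mu_ek electrokinetic mobility (m2 V-1 s-1).
#' @param mu_dep dielectrophoretic mobility (m4 V-2 s-1), non-zero.
#' @return ratio in V/m2.
#' @examples
#' ekmr(1e-8, -1e-18)   # 1e10
#' @export
ekmr <- function(mu_ek, mu_dep) {
  if (any(mu_dep == 0)) stop("mu_dep must be non-zero")
  mu_ek / abs(mu_dep)
}

#' Accessible EKMr dynamic range of a device
#'
#' Combines the voltage window `[v_lo, v_hi]` with the spatial spread of
#' per-gate centreline EKMr peaks: the lowest capturable ratio is the
#' weakest gate's peak at `v_lo`, the highest the strongest gate's peak at
#' `v_hi` (linear scaling in voltage). The voltage and spatial factors of
#' the span are reported separately.
#'
#' @param field a [solve_potential()] solution covering the gates of
#'   interest (solve the full channel for the whole-device range).
#' @param v_lo,v_hi applied-voltage window (V), `v_lo < v_hi`.
#' @return an object of class `dynamic_range`: `ekmr_min`, `ekmr_max`
#'   (V/m2), `orders_of_magnitude`, and the decomposition
#'   `voltage_factor` and `spatial_factor`.
#' @export
device_dynamic_range <- function(field, v_lo = 100, v_hi = 3000) {
  if (v_lo >= v_hi) stop("empty voltage window: v_lo must be < v_hi")
  if (v_lo <= 0) stop("voltages must be positive")
  pk <- gate_peaks(field)
  if (is.null(pk) || nrow(pk) < 1 || max(pk$ekmr_peak_Vpm2) <= 0) {
    stop("uniform field: no gate peaks to span a dynamic range")
  }
  per_volt <- pk$ekmr_peak_Vpm2 / field$applied_voltage
  lo <- min(per_volt) * v_lo
  hi <- max(per_volt) * v_hi
  structure(list(
    geometry = field$geometry$name,
    v_lo = v_lo, v_hi = v_hi,
    ekmr_min = lo, ekmr_max = hi,
    orders_of_magnitude = log10(hi / lo),
    voltage_factor = v_hi / v_lo,
    spatial_factor = max(per_volt) / min(per_volt),
    gate_peaks = pk
  ), class = "dynamic_range")
}

#' @export
print.dynamic_range <- function(x, ...) {
  cat(sprintf("EKMr dynamic range of %s over %g-%g V\n",
              x$geometry, x$v_lo, x$v_hi))
  cat(sprintf("  %.3g to %.3g V/m2: %.2f orders of magnitude\n",
              x$ekmr_min, x$ekmr_max, x$orders_of_magnitude))
  cat(sprintf("  decomposition: voltage factor %.3g x spatial factor %.3g\n",
              x$voltage_factor, x$spatial_factor))
  invisible(x)
}

#' Load a literature mobility table
#'
#' Reads a CSV with columns `taxon`, `strain`, `mu_ek_m2_per_Vs`,
#' `mu_dep_m4_per_V2s`, `source` (and optionally `ekmr_Vpm2`), validates
#' the records, and recomputes EKMr; a stored EKMr deviating from the
#' recomputed value by more than 0.1% triggers a warning.
#'
#' @param path CSV file path.
#' @return data frame of validated mobility records with a recomputed
#'   `ekmr_Vpm2` column.
#' @export
load_mobility_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "strain", "mu_ek_m2_per_Vs", "mu_dep_m4_per_V2s",
            "source")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("mobility table is missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(df$mu_dep_m4_per_V2s == 0 | df$mu_ek_m2_per_Vs == 0)
  if (length(bad)) {
    stop("zero mobility in row(s): ", paste(bad, collapse = ", "))
  }
  recomputed <- ekmr(df$mu_ek_m2_per_Vs, df$mu_dep_m4_per_V2s)
  if ("ekmr_Vpm2" %in% names(df)) {
    off <- abs(df$ekmr_Vpm2 - recomputed) > 1e-3 * abs(recomputed)
    if (any(off)) {
      warning("stored EKMr disagrees with recomputed value by >0.1% in ",
              "row(s): ", paste(which(off), collapse = ", "))
    }
  }
  df$ekmr_Vpm2 <- recomputed
  df
}

#' Plot-ready coordinates of mobility records
#'
#' One-dimensional mode collapses each record onto its EKMr value;
#' two-dimensional mode preserves the (mu_dep, mu_ek) pair. Records with
#' equal EKMr but different mobilities coincide in 1-D and separate in
#' 2-D, which is the motivation for the two-dimensional representation.
#'
#' @param records a [load_mobility_table()] data frame.
#' @param mode `"1d_ekmr"` or `"2d_mobility"`.
#' @return data frame of plot coordinates.
#' @export
map_records <- function(records, mode = c("1d_ekmr", "2d_mobility")) {
  mode <- match.arg(mode)
  if (!nrow(records)) stop("empty record set")
  label <- paste(records$taxon, records$strain)
  if (mode == "1d_ekmr") {
    data.frame(label = label, ekmr_Vpm2 = records$ekmr_Vpm2)
  } else {
    data.frame(label = label,
               mu_dep_m4_per_V2s = records$mu_dep_m4_per_V2s,
               mu_ek_m2_per_Vs = records$mu_ek_m2_per_Vs)
  }
}
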