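# Format round-tripping: CSV data tables, JSON summaries and sidecars,
# YAML/JSON geometry schema, legacy-ASCII VTK field export. Column names
# carry unit suffixes (voltage_V, mu_dep_m4_per_V2s, ...).

#' Write / read a voltage-sweep dataset as CSV
#'
#' Columns: `voltage_V`, `response`.
#'
#' @param dataset a [sweep_dataset()].
#' @param path CSV path.
#' @return `write_sweep_csv` returns `path` invisibly; `read_sweep_csv`
#'   returns a [sweep_dataset()].
#' @export
write_sweep_csv <- function(dataset, path) {
  utils::write.csv(data.frame(voltage_V = dataset$voltages,
                              response = dataset$responses),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("voltage_V", "response") %in% names(df))) {
    stop("sweep CSV must have columns voltage_V, response")
  }
  sweep_dataset(df$voltage_V, df$response)
}

#' Write / read a transition curve as CSV plus a JSON sidecar
#'
#' The CSV holds `x`, `percent_passed`; the sidecar (`<path>.json`) holds
#' the sweep variable and, when the curve admits one, the fitted
#' error-function parameters and partial range.
#'
#' @param curve a `transition_curve`.
#' @param path CSV path.
#' @return `path` invisibly / a `transition_curve`.
#' @export
write_transition_csv <- function(curve, path) {
  utils::write.csv(data.frame(x = curve$x_values,
                              percent_passed = curve$percent_passed),
                   path, row.names = FALSE)
  side <- list(variable = curve$variable)
  pr <- tryCatch(partial_range(curve), error = function(e) NULL)
  if (!is.null(pr)) side$partial_range <- pr
  ft <- tryCatch(fit_erf(curve), error = function(e) NULL)
  if (!is.null(ft)) {
    side$erf_fit <- list(center = ft$center, sigma = ft$sigma,
                         amplitude = ft$amplitude, baseline = ft$baseline)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_transition_csv
#' @export
read_transition_csv <- function(path) {
  df <- utils::read.csv(path)
  side_path <- paste0(path, ".json")
  variable <- "voltage"
  if (file.exists(side_path)) {
    variable <- jsonlite::read_json(side_path)$variable
  }
  transition_curve(df$x, df$percent_passed, variable = variable)
}

#' Export the centreline profile of a field solution as CSV
#'
#' Columns: `x_m`, `E_Vpm`, `gradE2_V2pm3`, `ekmr_Vpm2`.
#'
#' @param field a [solve_potential()] solution.
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_centerline_csv <- function(field, path) {
  utils::write.csv(ekmr_profile(field), path, row.names = FALSE)
  invisible(path)
}

#' Export a field solution as a legacy-ASCII VTK rectilinear grid
#'
#' Writes `potential_V`, `E_Vpm`, `gradE2x`, `gradE2y`, `ekmr_Vpm2` and
#' the fluid `mask` as point data on the cell-centre coordinates, readable
#' by ParaView and other VTK consumers.
#'
#' @param field a [solve_potential()] solution.
#' @param path output path (conventionally `.vtk`).
#' @return `path` invisibly.
#' @export
write_field_vtk <- function(field, path) {
  g <- field$grid
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("gidep field solution: ", field$geometry$name, " at ",
     format(field$applied_voltage), " V")
  wl("ASCII")
  wl("DATASET RECTILINEAR_GRID")
  wl(sprintf("DIMENSIONS %d %d 1", g$nx, g$ny))
  wl(sprintf("X_COORDINATES %d double", g$nx))
  wl(paste(format(g$x, digits = 10), collapse = " "))
  wl(sprintf("Y_COORDINATES %d double", g$ny))
  wl(paste(format(g$y, digits = 10), collapse = " "))
  wl("Z_COORDINATES 1 double")
  wl("0")
  wl(sprintf("POINT_DATA %d", g$nx * g$ny))
  dump_scalar <- function(name, M) {
    M[is.na(M)] <- 0
    wl(sprintf("SCALARS %s double 1", name))
    wl("LOOKUP_TABLE default")
    # VTK expects x fastest: our matrices are [y, x], so write row-wise
    writeLines(apply(M, 1, function(r) paste(format(r, digits = 8),
                                             collapse = " ")), con)
  }
  dump_scalar("potential_V", field$phi)
  dump_scalar("E_Vpm", field$Emag)
  dump_scalar("gradE2x_V2pm3", field$gradE2x)
  dump_scalar("gradE2y_V2pm3", field$gradE2y)
  dump_scalar("ekmr_Vpm2", field$ekmr)
  dump_scalar("mask", matrix(as.numeric(g$mask), g$ny, g$nx))
  invisible(path)
}

#' Write / read a geometry as a JSON (or YAML) schema
#'
#' The schema records the channel dimensions, wedge half-angle, and the
#' per-gate positions, gaps and tip radii, so custom geometries round-trip
#' exactly.
#'
#' @param geometry a [build_geometry()] object.
#' @param path output path; `.yaml`/`.yml` selects YAML (requires the
#'   `yaml` package), anything else JSON.
#' @return `path` invisibly / a `gidep_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  obj <- list(
    name = geometry$name,
    channel_length_m = geometry$channel_length,
    channel_width_m = geometry$channel_width,
    channel_height_m = geometry$channel_height,
    half_angle_deg = 180 / pi * geometry$half_angle,
    gates = list(position_m = geometry$gates$position,
                 gap_m = geometry$gates$gap,
                 tip_radius_m = geometry$gates$tip_radius)
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  build_geometry(
    gap_widths = as.numeric(obj$gates$gap_m),
    gate_positions = as.numeric(obj$gates$position_m),
    channel_width = obj$channel_width_m,
    channel_length = obj$channel_length_m,
    channel_height = obj$channel_height_m,
    half_angle = obj$half_angle_deg,
    tip_radius = if (length(obj$gates$tip_radius_m)) {
      max(as.numeric(obj$gates$tip_radius_m))
    } else 2e-6,
    name = obj$name
  )
}

#' Write an onset-voltage distribution as CSV plus a JSON summary
#'
#' @param dist an [run_onset_mc()] result.
#' @param path CSV path (one sample per row); the summary goes to
#'   `<path>.json`.
#' @return `path` invisibly.
#' @export
write_onset_distribution <- function(dist, path) {
  utils::write.csv(data.frame(onset_V = dist$samples), path,
                   row.names = FALSE)
  sm <- summary(dist)
  jsonlite::write_json(list(
    mean_V = sm$mean, sd_V = sm$sd, rsd_percent = sm$rsd_percent,
    quartiles_V = unname(sm$quartiles), nominal_onset_V = sm$nominal_onset,
    noise_level = sm$noise_level, n = sm$n
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# provenance stamp for pipeline outputs
provenance <- function(config, seed) {
  list(
    config_hash = digest_config(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("gidep")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}

# order-independent polynomial hash of a config list over its canonical
# deparse (stays within integer range for sprintf)
digest_config <- function(config) {
  config <- unclass(config)
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
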