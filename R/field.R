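# Finite-volume Laplace solver and derived electric-field quantities.
#
# The potential is solved on the masked tensor-product grid with Dirichlet
# values on the inlet/outlet faces of the modelled window and zero normal
# current on walls and insulator faces. For windowed solves the end-face
# potentials are apportioned from the applied channel voltage with the
# lumped 1-D resistance integral of the full geometry, which is exact in the
# straight leads where the window is cut.

# non-uniform first derivative along x for masked cell-centre data;
# one-sided where a neighbour is missing, optional Dirichlet ghost values
# on the domain's left/right faces.
ddx_mask <- function(M, x, dx, mask, bc_left = NULL, bc_right = NULL) {
  ny <- nrow(M); nx <- ncol(M)
  Ml <- cbind(NA_real_, M[, -nx, drop = FALSE])
  Mr <- cbind(M[, -1, drop = FALSE], NA_real_)
  al <- cbind(FALSE, mask[, -nx, drop = FALSE]) & mask
  ar <- cbind(mask[, -1, drop = FALSE], FALSE) & mask
  hl <- matrix(c(NA_real_, diff(x)), ny, nx, byrow = TRUE)
  hr <- matrix(c(diff(x), NA_real_), ny, nx, byrow = TRUE)
  if (!is.null(bc_left)) {
    Ml[, 1] <- bc_left; al[, 1] <- mask[, 1]; hl[, 1] <- dx[1] / 2
  }
  if (!is.null(bc_right)) {
    Mr[, nx] <- bc_right; ar[, nx] <- mask[, nx]; hr[, nx] <- dx[nx] / 2
  }
  out <- matrix(0, ny, nx)
  b <- al & ar
  out[b] <- (Mr[b] * hl[b]^2 + (hr[b]^2 - hl[b]^2) * M[b] - Ml[b] * hr[b]^2) /
    (hl[b] * hr[b] * (hl[b] + hr[b]))
  l <- al & !ar
  out[l] <- (M[l] - Ml[l]) / hl[l]
  r <- ar & !al
  out[r] <- (Mr[r] - M[r]) / hr[r]
  out[!mask] <- 0
  out
}

ddy_mask <- function(M, y, dy, mask, bc_bottom = NULL, bc_top = NULL) {
  t(ddx_mask(t(M), y, dy, t(mask), bc_left = bc_bottom, bc_right = bc_top))
}

# assemble the masked FV Laplacian; returns list(A, b, idx) for
# conductances sigma*h factored out (face conductance dy/dx_centre etc.)
assemble_laplace <- function(grid, phi_left, phi_right) {
  mask <- grid$mask; nx <- grid$nx; ny <- grid$ny
  idx <- matrix(0L, ny, nx)
  nfl <- sum(mask)
  idx[mask] <- seq_len(nfl)

  Hm <- mask[, -nx, drop = FALSE] & mask[, -1, drop = FALSE]
  hi <- row(Hm)[Hm]; hj <- col(Hm)[Hm]
  pH <- idx[cbind(hi, hj)]; qH <- idx[cbind(hi, hj + 1L)]
  fH <- grid$frac$fH[cbind(hi, hj)]
  gH <- fH * grid$dy[hi] / ((grid$dx[hj] + grid$dx[hj + 1L]) / 2)

  Vm <- mask[-ny, , drop = FALSE] & mask[-1, , drop = FALSE]
  vi <- row(Vm)[Vm]; vj <- col(Vm)[Vm]
  pV <- idx[cbind(vi, vj)]; qV <- idx[cbind(vi + 1L, vj)]
  fV <- grid$frac$fV[cbind(vi, vj)]
  gV <- fV * grid$dx[vj] / ((grid$dy[vi] + grid$dy[vi + 1L]) / 2)

  iL <- which(mask[, 1]); pL <- idx[cbind(iL, 1L)]
  gL <- grid$dy[iL] / (grid$dx[1] / 2)
  iR <- which(mask[, nx]); pR <- idx[cbind(iR, nx)]
  gR <- grid$dy[iR] / (grid$dx[nx] / 2)

  ii <- c(pH, qH, pH, qH, pV, qV, pV, qV, pL, pR)
  jj <- c(pH, qH, qH, pH, pV, qV, qV, pV, pL, pR)
  xx <- c(gH, gH, -gH, -gH, gV, gV, -gV, -gV, gL, gR)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nfl, nfl))
  b <- numeric(nfl)
  b[pL] <- gL * phi_left
  b[pR] <- b[pR] + gR * phi_right
  list(A = A, b = b, idx = idx,
       faces = list(hi = hi, hj = hj, pH = pH, qH = qH, gH = gH,
                    vi = vi, vj = vj, pV = pV, qV = qV, gV = gV,
                    iL = iL, pL = pL, gL = gL, iR = iR, pR = pR, gR = gR))
}

#' Solve the electric potential in a gated channel
#'
#' Solves the Laplace equation for the potential on a (windowed) gated
#' channel with a five-point finite-volume discretization: Dirichlet
#' potential on the inlet and outlet faces, zero normal current on walls and
#' insulator faces. Windowed solves receive end-face potentials from the
#' lumped axial resistance of the full channel, so `applied_voltage` always
#' refers to the potential applied across the whole device.
#'
#' The returned solution carries the field magnitude `Emag`, the gradient of
#' the squared field `gradE2x`/`gradE2y` (central differences of `|E|^2`,
#' one-sided at boundaries) and the local electrokinetic mobility ratio
#' field `ekmr = |grad E^2| / |E|` (V/m2), whose centreline maxima at the
#' gates set capture onset.
#'
#' @param geometry a [build_geometry()] object.
#' @param applied_voltage potential across the whole channel (V), > 0.
#' @param params a [physical_params()] object.
#' @param resolution,window,uniform,margin passed to [rasterize()] when
#'   `grid` is not supplied.
#' @param grid optionally a pre-built [rasterize()] grid.
#' @return An object of class `gidep_field` with matrices `phi`, `Ex`, `Ey`,
#'   `Emag`, `gradE2x`, `gradE2y`, `ekmr` on the grid, the end-face
#'   potentials `phi_window`, and the absolute through-current `current` (A).
#' @examples
#' geo <- build_geometry(gap_widths = 100e-6, channel_length = 2e-3,
#'                       gate_positions = 1e-3, channel_width = 250e-6)
#' f <- solve_potential(geo, 100, resolution = 8)
#' max(f$ekmr, na.rm = TRUE) > 0
#' @export
solve_potential <- function(geometry, applied_voltage, params = physical_params(),
                            resolution = 10, window = NULL, uniform = FALSE,
                            margin = NULL, grid = NULL) {
  stopifnot(applied_voltage > 0)
  if (is.null(grid)) {
    grid <- rasterize(geometry, resolution = resolution, window = window,
                      uniform = uniform, margin = margin)
  }
  Rtot <- channel_resistance(geometry)
  RL <- channel_resistance(geometry, 0, grid$x_lo)
  RR <- channel_resistance(geometry, 0, grid$x_hi)
  phi_left <- applied_voltage * (1 - RL / Rtot)
  phi_right <- applied_voltage * (1 - RR / Rtot)

  asm <- assemble_laplace(grid, phi_left, phi_right)
  sol <- tryCatch(
    as.numeric(Matrix::solve(Matrix::forceSymmetric(asm$A), asm$b)),
    error = function(e) stop("potential solve failed: ", conditionMessage(e))
  )
  if (any(!is.finite(sol))) stop("potential solve failed: non-finite solution")
  phi <- matrix(NA_real_, grid$ny, grid$nx)
  phi[grid$mask] <- sol

  Ex <- -ddx_mask(phi, grid$x, grid$dx, grid$mask, phi_left, phi_right)
  Ey <- -ddy_mask(phi, grid$y, grid$dy, grid$mask)
  E2 <- Ex^2 + Ey^2
  Emag <- sqrt(E2)
  gx <- ddx_mask(E2, grid$x, grid$dx, grid$mask)
  gy <- ddy_mask(E2, grid$y, grid$dy, grid$mask)
  ekmr <- sqrt(gx^2 + gy^2) / pmax(Emag, .Machine$double.eps)
  ekmr[!grid$mask] <- 0

  sigma_h <- params$conductivity * geometry$channel_height
  fl <- asm$faces
  cur <- section_current_vector(phi, grid, fl, phi_left, phi_right) * sigma_h

  structure(list(
    grid = grid, geometry = geometry, params = params,
    applied_voltage = applied_voltage,
    phi_window = c(inlet = phi_left, outlet = phi_right),
    phi = phi, Ex = Ex, Ey = Ey, Emag = Emag, E2 = E2,
    gradE2x = gx, gradE2y = gy, ekmr = ekmr,
    current = cur, faces = fl
  ), class = "gidep_field")
}

# per-interface through-current (units of conductance*volt, i.e. before the
# sigma*h scaling): interfaces 0..nx between columns, including end faces.
section_current_vector <- function(phi, grid, fl, phi_left, phi_right) {
  phiv <- phi
  fH <- fl$gH * (phiv[cbind(fl$hi, fl$hj)] - phiv[cbind(fl$hi, fl$hj + 1L)])
  interior <- as.numeric(tapply(fH, factor(fl$hj, levels = seq_len(grid$nx - 1L)),
                                sum, default = 0))
  inflow <- sum(fl$gL * (phi_left - phiv[cbind(fl$iL, 1L)]))
  outflow <- sum(fl$gR * (phiv[cbind(fl$iR, grid$nx)] - phi_right))
  c(inflow, interior, outflow)
}

#' Through-current at every cross-section of a field solution
#'
#' @param field a [solve_potential()] solution.
#' @return numeric vector of absolute currents (A) at the inlet face, every
#'   interior column interface, and the outlet face. Charge conservation
#'   requires these to agree.
#' @export
section_currents <- function(field) {
  field$current
}

#' Electroosmotic flow field
#'
#' Returns the fluid velocity on the grid. In `"similitude"` mode the
#' velocity is `mu_ek * E`, exact for insulating walls, uniform wall charge
#' and thin double layers. In `"stokes"` mode the creeping-flow limit with
#' electroosmotic wall slip is solved via its streamfunction (the flow is
#' irrotational under the same wall conditions), giving a discretely
#' divergence-free field; the volumetric rate is fixed by the through-current.
#'
#' @param field a [solve_potential()] solution.
#' @param params a [physical_params()] object; `mu_ek` sets the slip.
#' @param mode `"similitude"` (default) or `"stokes"`.
#' @return list with velocity matrices `ux`, `uy` (m/s), the `mode`, and for
#'   stokes mode the streamfunction `psi` and flow rate `Q` (m2/s per unit
#'   depth).
#' @export
flow_field <- function(field, params = field$params,
                       mode = c("similitude", "stokes")) {
  mode <- match.arg(mode)
  grid <- field$grid
  if (mode == "similitude") {
    return(list(ux = params$mu_ek * field$Ex, uy = params$mu_ek * field$Ey,
                mode = mode))
  }
  # streamfunction: Laplace solve with psi = 0 on the bottom wall/insulators,
  # psi = Q on the top, zero normal derivative at inlet/outlet.
  Q <- params$mu_ek * mean(field$current) /
    (field$params$conductivity * field$geometry$channel_height)
  mask <- grid$mask; nx <- grid$nx; ny <- grid$ny
  idx <- matrix(0L, ny, nx); nfl <- sum(mask); idx[mask] <- seq_len(nfl)

  Hm <- mask[, -nx, drop = FALSE] & mask[, -1, drop = FALSE]
  hi <- row(Hm)[Hm]; hj <- col(Hm)[Hm]
  pH <- idx[cbind(hi, hj)]; qH <- idx[cbind(hi, hj + 1L)]
  gH <- grid$dy[hi] / ((grid$dx[hj] + grid$dx[hj + 1L]) / 2)
  Vm <- mask[-ny, , drop = FALSE] & mask[-1, , drop = FALSE]
  vi <- row(Vm)[Vm]; vj <- col(Vm)[Vm]
  pV <- idx[cbind(vi, vj)]; qV <- idx[cbind(vi + 1L, vj)]
  gV <- grid$dx[vj] / ((grid$dy[vi] + grid$dy[vi + 1L]) / 2)

  # wall Dirichlet faces: fluid cell with solid/domain-boundary neighbour in y
  below_solid <- mask & rbind(TRUE, !mask[-ny, , drop = FALSE])
  above_solid <- mask & rbind(!mask[-1, , drop = FALSE], TRUE)
  bi <- row(below_solid)[below_solid]; bj <- col(below_solid)[below_solid]
  pB <- idx[cbind(bi, bj)]; gB <- grid$dx[bj] / (grid$dy[bi] / 2)
  ti <- row(above_solid)[above_solid]; tj <- col(above_solid)[above_solid]
  pT <- idx[cbind(ti, tj)]; gT <- grid$dx[tj] / (grid$dy[ti] / 2)

  ii <- c(pH, qH, pH, qH, pV, qV, pV, qV, pB, pT)
  jj <- c(pH, qH, qH, pH, pV, qV, qV, pV, pB, pT)
  xx <- c(gH, gH, -gH, -gH, gV, gV, -gV, -gV, gB, gT)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nfl, nfl))
  b <- numeric(nfl)
  b[pB] <- b[pB] + gB * 0
  btop <- numeric(nfl); btop[pT] <- gT * Q
  b <- b + btop
  sol <- as.numeric(Matrix::solve(Matrix::forceSymmetric(A), b))
  psi <- matrix(NA_real_, ny, nx); psi[mask] <- sol
  # fill solid cells with their wall streamfunction value, then form corner
  # values and face velocities: the FV divergence of the resulting field
  # telescopes to zero exactly.
  psifull <- psi
  solid_bottom <- !mask & matrix(grid$y < 0, ny, nx)
  psifull[solid_bottom] <- 0
  psifull[!mask & !solid_bottom] <- Q
  # mirror ghosts across the channel walls so wall corners carry the exact
  # wall streamfunction value
  pad <- rbind(-psifull[1, ], psifull, 2 * Q - psifull[ny, ])
  pad <- cbind(pad[, 1], pad, pad[, nx])
  corner <- (pad[-(ny + 2L), -(nx + 2L)] + pad[-(ny + 2L), -1] +
             pad[-1, -(nx + 2L)] + pad[-1, -1]) / 4   # (ny+1) x (nx+1)
  # x-velocity on vertical faces (ny x nx+1), y-velocity on horizontal faces
  u_face <- (corner[-1, ] - corner[-(ny + 1L), ]) / grid$dy
  v_face <- -(corner[, -1] - corner[, -(nx + 1L)]) /
    matrix(grid$dx, ny + 1L, nx, byrow = TRUE)
  ux <- (u_face[, -1] + u_face[, -(nx + 1L)]) / 2
  uy <- (v_face[-1, ] + v_face[-(ny + 1L), ]) / 2
  ux[!mask] <- 0; uy[!mask] <- 0
  list(ux = ux, uy = uy, psi = psi, Q = Q, mode = mode,
       u_face = u_face, v_face = v_face)
}

#' Discrete divergence of a flow field
#'
#' Finite-volume divergence per cell, normalized by the mean fluid speed
#' over the cell size. For `"stokes"` flows the face-based construction is
#' divergence free by design; for `"similitude"` flows the divergence
#' reflects the discretization error of the underlying Laplace solve.
#'
#' @param flow a [flow_field()] result.
#' @param grid the grid the flow was computed on.
#' @return matrix of normalized divergence values (dimensionless).
#' @export
flow_divergence <- function(flow, grid) {
  ny <- grid$ny; nx <- grid$nx
  if (!is.null(flow$u_face)) {
    dxm <- matrix(grid$dx, ny, nx, byrow = TRUE)
    dym <- matrix(grid$dy, ny, nx)
    div <- (flow$u_face[, -1, drop = FALSE] - flow$u_face[, -(nx + 1L), drop = FALSE]) / dxm +
           (flow$v_face[-1, , drop = FALSE] - flow$v_face[-(ny + 1L), , drop = FALSE]) / dym
  } else {
    div <- ddx_mask(flow$ux, grid$x, grid$dx, grid$mask) +
           ddy_mask(flow$uy, grid$y, grid$dy, grid$mask)
  }
  sp <- sqrt(flow$ux^2 + flow$uy^2)
  h <- sqrt(outer(grid$dy, grid$dx))
  out <- div * h / max(mean(sp[grid$mask]), .Machine$double.eps)
  out[!grid$mask] <- 0
  out
}

#' Centreline profile of field-derived quantities
#'
#' Extracts the channel centreline (average of the two cell rows straddling
#' y = 0) profile of `|E|`, `|grad E^2|` and the EKMr ratio versus axial
#' position. The EKMr maxima sit at the gate constrictions; capture of a
#' particle with mobilities `mu_ek`, `mu_dep` begins where the centreline
#' ratio reaches `mu_ek / |mu_dep|`.
#'
#' @param field a [solve_potential()] solution.
#' @return data frame with columns `x_m`, `E_Vpm`, `gradE2_V2pm3`,
#'   `ekmr_Vpm2`.
#' @export
ekmr_profile <- function(field) {
  grid <- field$grid
  i0 <- max(which(grid$y < 0)); i1 <- i0 + 1L
  if (i1 > grid$ny) i1 <- i0
  keep <- grid$mask[i0, ] & grid$mask[i1, ]
  if (!any(keep)) stop("centreline exits the fluid domain")
  gE2 <- sqrt(field$gradE2x^2 + field$gradE2y^2)
  data.frame(
    x_m = grid$x[keep],
    E_Vpm = (field$Emag[i0, keep] + field$Emag[i1, keep]) / 2,
    gradE2_V2pm3 = (gE2[i0, keep] + gE2[i1, keep]) / 2,
    ekmr_Vpm2 = (field$ekmr[i0, keep] + field$ekmr[i1, keep]) / 2
  )
}

#' Per-gate centreline EKMr peaks
#'
#' @param field a [solve_potential()] solution.
#' @return data frame with one row per gate inside the solved window:
#'   `gate`, `gap_m`, `x_peak_m`, `ekmr_peak_Vpm2`, `gradE2_peak_V2pm3`,
#'   `E_peak_Vpm`.
#' @export
gate_peaks <- function(field) {
  prof <- ekmr_profile(field)
  geo <- field$geometry
  gates <- if (is.null(field$grid$window)) seq_len(geo$n_gates) else
    seq.int(field$grid$window[1], field$grid$window[2])
  out <- do.call(rbind, lapply(gates, function(k) {
    p <- geo$gates$position[k]
    f <- gate_footprint(geo, k)
    sel <- prof$x_m >= p - f & prof$x_m <= p + f
    if (!any(sel)) return(NULL)
    i <- which.max(prof$ekmr_Vpm2[sel])
    sub <- prof[sel, ][i, ]
    data.frame(gate = k, gap_m = geo$gates$gap[k], x_peak_m = sub$x_m,
               ekmr_peak_Vpm2 = sub$ekmr_Vpm2,
               gradE2_peak_V2pm3 = max(prof$gradE2_V2pm3[sel]),
               E_peak_Vpm = max(prof$E_Vpm[sel]))
  }))
  rownames(out) <- NULL
  out
}

#' Find the voltage that matches peak gap field gradients across devices
#'
#' Given reference field solutions for two devices, returns the voltage to
#' apply to the second device so that its peak centreline `|grad E^2|` at
#' the gates equals that of the first device at `v_a`. Uses the exact
#' quadratic scaling of `grad E^2` with applied voltage.
#'
#' @param field_a,field_b reference [solve_potential()] solutions.
#' @param v_a applied voltage (V) on device A.
#' @return list with `v_b`, the matched voltage (V), and `ratio`, the
#'   achieved peak-gradient ratio A/B at (`v_a`, `v_b`) (1 up to numerical
#'   precision).
#' @export
match_gradient <- function(field_a, field_b, v_a) {
  ga <- max(gate_peaks(field_a)$gradE2_peak_V2pm3) / field_a$applied_voltage^2
  gb <- max(gate_peaks(field_b)$gradE2_peak_V2pm3) / field_b$applied_voltage^2
  v_b <- v_a * sqrt(ga / gb)
  list(v_b = v_b, ratio = (ga * v_a^2) / (gb * v_b^2))
}

#' @export
print.gidep_field <- function(x, ...) {
  cat(sprintf("gidep field solution: %s at %.4g V\n", x$geometry$name,
              x$applied_voltage))
  cat(sprintf("  window faces at %.4g / %.4g V, current %.3g A\n",
              x$phi_window[1], x$phi_window[2], mean(x$current)))
  pk <- try(max(ekmr_profile(x)$ekmr_Vpm2), silent = TRUE)
  if (!inherits(pk, "try-error")) {
    cat(sprintf("  peak centreline EKMr: %.4g V/m2\n", pk))
  }
  invisible(x)
}
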