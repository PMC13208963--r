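# Stationary convection-diffusion capture model.
#
# Particle concentration obeys div(-D grad c + v c) = 0 (no source, R = 0)
# with v = u + mu_dep * grad(E^2): electrokinetic carriage by the flow plus
# the dielectrophoretic drift. The inlet carries a fixed concentration, the
# outlet is a pure-outflow boundary, walls and insulators are no-flux. For
# negative-DEP particles the drift focuses the beam towards the centreline
# at every gate while diffusion (deliberately inflated, see the vignette)
# re-spreads it in between, so a focused equilibrium beam arrives at the
# terminal gate set.
#
# Capture at the readout gate is read from that arriving beam: the drift
# reverses (v_x < 0) upstream of the gate tips once the voltage is high
# enough, and the reversed basin grows towards the centreline as voltage or
# |mu_dep| rises. Each arriving streamline has a blocking voltage V_b at
# which its path meets the basin; the percent passed is the flux fraction
# of the arriving concentration on streamlines that are still open. This
# reproduces the observed behaviour that identical particles partially pass
# over a finite voltage range set jointly by the gate geometry and the
# beam width.

# Face coefficients of the exponential-fitting (Scharfetter-Gummel) flux
# F = am * c_upstream - ap * c_downstream. Beyond |Pe| = 30 the exact
# coefficients underflow and make rows of the transport matrix numerically
# dependent, so the scheme switches to pure upwinding with a relative
# back-coupling of 1e-10, which leaves the resolved fluxes unchanged to
# that tolerance while keeping the matrix well conditioned.
sg_coeffs <- function(Af, Dd, pe, pe_cap = 30) {
  am <- Af * Dd * bernoulli_sg(-pmin(pmax(pe, -pe_cap), pe_cap))
  ap <- Af * Dd * bernoulli_sg(pmin(pmax(pe, -pe_cap), pe_cap))
  v <- pe * Dd
  big <- abs(pe) > pe_cap
  if (any(big)) {
    adv <- Af[big] * abs(v[big])
    pos <- pe[big] > 0
    am[big] <- ifelse(pos, adv, adv * 1e-10)
    ap[big] <- ifelse(pos, adv * 1e-10, adv)
  }
  list(am = am, ap = ap)
}

# Scharfetter-Gummel / exponential-fitting flux factor, numerically safe.
bernoulli_sg <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-10
  out[small] <- 1 - x[small] / 2
  big <- x > 700
  out[big] <- 0
  neg <- x < -700
  out[neg] <- -x[neg]
  rest <- !(small | big | neg)
  out[rest] <- x[rest] / expm1(x[rest])
  out
}

#' Solve stationary convection-diffusion transport with DEP drift
#'
#' Discretizes the stationary convection-diffusion equation on the field's
#' grid with exponential-fitting (Scharfetter-Gummel) face fluxes, which
#' remain stable and positivity-preserving at the high cell Peclet numbers
#' the capture problem produces. Boundary conditions: inlet concentration 1,
#' advective outflow at the outlet, zero flux on walls and insulators. The
#' drift velocity is `flow + mu_dep * grad(E^2)`.
#'
#' @param field a [solve_potential()] solution (possibly rescaled via
#'   [scale_field()]).
#' @param params a [physical_params()] object supplying `mu_dep`, `mu_ek`
#'   and the diffusion coefficient.
#' @param flow optional [flow_field()] result; defaults to electroosmotic
#'   similitude flow at `params$mu_ek`.
#' @param readout_gate gate index at which capture is read; default: the
#'   geometry's third-to-last gate (the published protocol records after
#'   gate 25 of the 27-gate large-gap design). Must lie inside the solved
#'   window.
#' @param absorb `"none"` (default) solves the literal source-free
#'   stationary problem and reads capture as the flux fraction of the
#'   arriving beam whose drift path clears the readout gate;
#'   `"basin"` additionally holds the reversed-drift capture basins at
#'   c = 0 and reads capture as the flux crossing the readout line over the
#'   unobstructed influx (the stationary first-passage formulation matched
#'   by [particle_tracking_oracle()]).
#' @return An object of class `gidep_transport`: concentration matrix `c`
#'   (inlet-normalized), `percent_passed`, `inlet_flux` (unobstructed
#'   reference influx), `outlet_flux` (flux across the readout line),
#'   `readout_x`, `max_cell_peclet`, and references to field and
#'   parameters.
#' @export
solve_transport <- function(field, params = field$params, flow = NULL,
                            readout_gate = NULL, absorb = c("none", "basin")) {
  absorb <- match.arg(absorb)
  grid <- field$grid
  D <- params$diffusion_coefficient
  if (D <= 0) stop("diffusion coefficient must be positive")
  if (is.null(flow)) flow <- flow_field(field, params, mode = "similitude")
  vx <- flow$ux + params$mu_dep * field$gradE2x
  vy <- flow$uy + params$mu_dep * field$gradE2y

  mask <- grid$mask; nx <- grid$nx; ny <- grid$ny
  idx <- matrix(0L, ny, nx); nfl <- sum(mask); idx[mask] <- seq_len(nfl)

  # interior x-faces
  Hm <- mask[, -nx, drop = FALSE] & mask[, -1, drop = FALSE]
  hi <- row(Hm)[Hm]; hj <- col(Hm)[Hm]
  pH <- idx[cbind(hi, hj)]; qH <- idx[cbind(hi, hj + 1L)]
  fH <- grid$frac$fH[cbind(hi, hj)]
  AfH <- fH * grid$dy[hi]
  dH <- (grid$dx[hj] + grid$dx[hj + 1L]) / 2
  vH <- (vx[cbind(hi, hj)] + vx[cbind(hi, hj + 1L)]) / 2
  peH <- vH * dH / D
  cf <- sg_coeffs(AfH, D / dH, peH)
  aHm <- cf$am   # multiplies upstream cell (P)
  aHp <- cf$ap   # multiplies downstream cell (N)

  # interior y-faces
  Vm <- mask[-ny, , drop = FALSE] & mask[-1, , drop = FALSE]
  vi <- row(Vm)[Vm]; vj <- col(Vm)[Vm]
  pV <- idx[cbind(vi, vj)]; qV <- idx[cbind(vi + 1L, vj)]
  fV <- grid$frac$fV[cbind(vi, vj)]
  AfV <- fV * grid$dx[vj]
  dV <- (grid$dy[vi] + grid$dy[vi + 1L]) / 2
  vV <- (vy[cbind(vi, vj)] + vy[cbind(vi + 1L, vj)]) / 2
  peV <- vV * dV / D
  cf <- sg_coeffs(AfV, D / dV, peV)
  aVm <- cf$am; aVp <- cf$ap

  # inlet: Dirichlet c = 1 at the left face
  iL <- which(mask[, 1]); pL <- idx[cbind(iL, 1L)]
  AfL <- grid$dy[iL]; dL <- grid$dx[1] / 2
  vL <- vx[cbind(iL, 1L)]
  peL <- vL * dL / D
  cf <- sg_coeffs(AfL, D / dL, peL)
  aLm <- cf$am   # multiplies ghost (c = 1)
  aLp <- cf$ap   # multiplies first cell

  # outlet: advective outflow only
  iR <- which(mask[, nx]); pR <- idx[cbind(iR, nx)]
  aR <- grid$dy[iR] * pmax(vx[cbind(iR, nx)], 0)

  ii <- c(pH, pH, qH, qH, pV, pV, qV, qV, pL, pR)
  jj <- c(pH, qH, pH, qH, pV, qV, pV, qV, pL, pR)
  xx <- c(aHm, -aHp, -aHm, aHp, aVm, -aVp, -aVm, aVp, aLp, aR)
  b <- numeric(nfl)
  b[pL] <- aLm * 1
  if (absorb == "basin") {
    # hold the reversed-drift capture basins at c = 0: particles that
    # reach them leave the flowing phase
    trap <- which(vx[mask] < 0)
    if (length(trap)) {
      keep <- !(ii %in% trap)
      ii <- c(ii[keep], trap); jj <- c(jj[keep], trap)
      xx <- c(xx[keep], rep(1, length(trap)))
      b[trap] <- 0
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nfl, nfl))
  # cells at the stagnation nose of a barrier receive inflow on every face
  # and their upwinded rows vanish at high cell Peclet; they sit on the
  # capture surface, so hold them at c = 0 as well
  rmax <- (abs(A) %*% rep(1, nfl))[, 1]
  dead <- which(rmax < 1e-10 * stats::median(rmax))
  if (length(dead)) {
    keep <- !(A@i + 1L) %in% dead
    A <- Matrix::sparseMatrix(i = (A@i + 1L)[keep],
                              j = rep(seq_len(nfl), diff(A@p))[keep],
                              x = A@x[keep], dims = c(nfl, nfl)) +
      Matrix::sparseMatrix(i = dead, j = dead, x = rep(1, length(dead)),
                           dims = c(nfl, nfl))
    b[dead] <- 0
    rmax <- (abs(A) %*% rep(1, nfl))[, 1]
  }
  # row equilibration: face coefficients span many orders of magnitude at
  # high cell Peclet
  rs <- 1 / pmax(rmax, .Machine$double.xmin)
  A <- Matrix::Diagonal(x = rs) %*% A
  b <- rs * b

  sol <- tryCatch(as.numeric(Matrix::solve(A, b)), error = function(e) {
    stop("transport solve failed (max cell Peclet ",
         signif(max(abs(c(peH, peV))), 3), "): ", conditionMessage(e))
  })
  if (any(!is.finite(sol))) {
    stop("transport solve returned non-finite concentrations (max cell Peclet ",
         signif(max(abs(c(peH, peV))), 3), ")")
  }
  cc <- matrix(NA_real_, ny, nx)
  cc[mask] <- sol
  if (min(sol) < -1e-3) {
    warning("concentration undershoot beyond tolerance: min c = ", signif(min(sol), 3))
  }

  # reference (unobstructed) influx and readout-line flux
  inlet_flux <- sum(AfL * pmax(vL, 0))
  geo <- field$geometry
  if (is.null(readout_gate)) {
    readout_gate <- max(1L, geo$n_gates - 2L)
    if (!is.null(grid$window)) {
      readout_gate <- min(max(readout_gate, grid$window[1]), grid$window[2])
    }
  }
  if (!is.null(grid$window) &&
      (readout_gate < grid$window[1] || readout_gate > grid$window[2])) {
    stop("readout_gate lies outside the solved window")
  }
  x_rec <- readout_position(geo, readout_gate, grid)
  j0 <- which.min(abs(grid$xf[2:nx] - x_rec))   # face between cols j0, j0+1
  sel <- hj == j0
  outlet_flux <- sum(aHm[sel] * sol[pH[sel]] - aHp[sel] * sol[qH[sel]])

  if (absorb == "basin" || geo$n_gates == 0L) {
    # first-passage readout: surviving flux over unobstructed influx
    # (also the natural readout for a gate-free channel)
    pct <- min(max(100 * outlet_flux / inlet_flux, 0), 100)
  } else {
    # capture readout: flux fraction of the beam arriving at the readout
    # gate's entrance plane that survives the passage (drift path clears
    # the reversed-drift basin and escapes diffusive capture into it)
    p0 <- geo$gates$position[readout_gate]
    f0 <- gate_footprint(geo, readout_gate)
    je0 <- which.min(abs(grid$x - max(p0 - 1.15 * f0, grid$x_lo)))
    rows0 <- which(grid$mask[, je0])
    fe <- pmax(vx[cbind(rows0, je0)], 0) * cc[cbind(rows0, je0)] *
      grid$dy[rows0]
    om <- gate_open_rows(field, vx, vy, readout_gate, D, weights = fe)
    arriving <- sum(fe)
    pct <- if (arriving > 0) min(max(100 * sum(fe * om$surv) / arriving, 0), 100) else 0
  }

  structure(list(
    c = cc, percent_passed = pct,
    inlet_flux = inlet_flux, outlet_flux = outlet_flux,
    readout_gate = readout_gate, readout_x = grid$xf[j0 + 1L],
    max_cell_peclet = max(abs(c(peH, peV))),
    min_concentration = min(sol), max_concentration = max(sol),
    field = field, params = params
  ), class = "gidep_transport")
}

# Transmission of the readout gate for each arriving streamline: trace the
# total-drift path of each entrance row through the gate. A path that
# enters the reversed-drift basin (v_x < 0) or stalls is captured
# (survival 0); an open path passing the absorbing basin at distance
# delta(t) accumulates the diffusive-capture exposure integral
# E = int D dt / delta(t)^2 and survives with probability exp(-E)
# (absorbing boundary-layer approximation: only the stretch where the
# path grazes the basin contributes). Returns the entrance plane column,
# its fluid rows, and per-row survival probabilities.
gate_open_rows <- function(field, vx, vy, readout_gate, D, weights = NULL,
                           subseeds = 4L) {
  grid <- field$grid; geo <- field$geometry
  p <- geo$gates$position[readout_gate]
  f <- gate_footprint(geo, readout_gate)
  x_e <- max(p - 1.15 * f, grid$x_lo)
  x_end <- min(p + 1.15 * f, grid$x_hi)
  je <- which.min(abs(grid$x - x_e))
  rows <- which(grid$mask[, je])
  vxm <- vx; vym <- vy
  vxm[!grid$mask] <- 0; vym[!grid$mask] <- 0
  interp <- function(M, xs, ys) {
    jx <- pmin(pmax(findInterval(xs, grid$x), 1L), grid$nx - 1L)
    iy <- pmin(pmax(findInterval(ys, grid$y), 1L), grid$ny - 1L)
    tx <- pmin(pmax((xs - grid$x[jx]) / (grid$x[jx + 1L] - grid$x[jx]), 0), 1)
    ty <- pmin(pmax((ys - grid$y[iy]) / (grid$y[iy + 1L] - grid$y[iy]), 0), 1)
    M[cbind(iy, jx)] * (1 - tx) * (1 - ty) + M[cbind(iy, jx + 1L)] * tx * (1 - ty) +
      M[cbind(iy + 1L, jx)] * (1 - tx) * ty + M[cbind(iy + 1L, jx + 1L)] * tx * ty
  }
  # distance-to-basin field, restricted to the basin's neighbourhood (the
  # exposure integrand decays as 1/d^2, so remote cells keep distance Inf)
  near <- which(grid$x >= x_e - 2 * f & grid$x <= x_end + f)
  basinM <- grid$mask & (vxm < 0)
  basinM[, -near] <- FALSE
  bi <- which(basinM, arr.ind = TRUE)
  distf <- matrix(Inf, grid$ny, grid$nx)
  if (nrow(bi)) {
    bx <- grid$x[bi[, 2]]; by <- grid$y[bi[, 1]]
    if (nrow(bi) > 400) {   # subsample large basins; spacing error is O(h)
      keep <- seq(1, nrow(bi), length.out = 400)
      bx <- bx[keep]; by <- by[keep]
    }
    pad <- 6 * max(grid$geometry$gates$gap[readout_gate],
                   max(grid$dy))
    jj <- which(grid$x >= min(bx) - pad & grid$x <= max(bx) + pad)
    ii2 <- which(grid$y >= min(by) - pad & grid$y <= max(by) + pad)
    sub <- as.matrix(expand.grid(i = ii2, j = jj))
    d2 <- outer(grid$x[sub[, 2]], bx, `-`)^2 +
      outer(grid$y[sub[, 1]], by, `-`)^2
    distf[sub] <- sqrt(d2[cbind(seq_len(nrow(d2)), max.col(-d2))])
  }

  # several sub-seeds per entrance row: the open/blocked boundary then
  # moves in sub-row steps instead of flipping whole rows of beam flux
  q <- max(1L, as.integer(subseeds))
  off <- ((seq_len(q) - 0.5) / q - 0.5)
  rows_s <- rep(rows, each = q)
  n <- length(rows_s)
  px <- rep(grid$x[je], n)
  py <- grid$y[rows_s] + rep(off, length(rows)) * grid$dy[rows_s]
  surv <- rep(0, n)
  expo <- rep(0, n)
  active <- rep(TRUE, n)
  # sub-seeds carrying negligible arriving flux are not traced (their
  # survival cannot move the flux-weighted percentage)
  if (!is.null(weights) && sum(weights) > 0) {
    skip <- rep(weights, each = q) < 1e-5 * sum(weights)
    surv[skip] <- 1
    active[skip] <- FALSE
  }
  vref <- stats::median(abs(vxm[cbind(rows, je)]))
  step_len <- function(xs, ys, cx, cy) {
    dxl <- grid$dx[pmin(pmax(findInterval(xs, grid$xf), 1L), grid$nx)]
    dyl <- grid$dy[pmin(pmax(findInterval(ys, grid$yf), 1L), grid$ny)]
    0.45 * (dxl * abs(cx) + dyl * abs(cy))
  }
  maxit <- 40L * grid$nx
  for (it in seq_len(maxit)) {
    id <- which(active)
    if (!length(id)) break
    u1 <- interp(vxm, px[id], py[id]); v1 <- interp(vym, px[id], py[id])
    s1 <- sqrt(u1^2 + v1^2)
    blocked <- u1 < 0 | s1 < 1e-9 * vref
    if (any(blocked)) {
      active[id[blocked]] <- FALSE
      id <- id[!blocked]; u1 <- u1[!blocked]; v1 <- v1[!blocked]; s1 <- s1[!blocked]
      if (!length(id)) next
    }
    ds <- step_len(px[id], py[id], u1 / s1, v1 / s1)
    mx <- px[id] + ds / 2 * u1 / s1; my <- py[id] + ds / 2 * v1 / s1
    u2 <- interp(vxm, mx, my); v2 <- interp(vym, mx, my)
    s2 <- sqrt(u2^2 + v2^2)
    b2 <- u2 < 0 | s2 < 1e-9 * vref
    if (any(b2)) {
      active[id[b2]] <- FALSE
      id <- id[!b2]; u2 <- u2[!b2]; v2 <- v2[!b2]; s2 <- s2[!b2]; ds <- ds[!b2]
      if (!length(id)) next
    }
    px[id] <- px[id] + ds * u2 / s2
    py[id] <- py[id] + ds * v2 / s2
    w <- channel_halfwidth(geo, px[id])
    py[id] <- pmin(pmax(py[id], -w * (1 - 1e-9)), w * (1 - 1e-9))
    dloc <- interp(distf, px[id], py[id])
    expo[id] <- expo[id] + ifelse(is.finite(dloc),
                                  D * (ds / s2) / pmax(dloc, 1e-12)^2, 0)
    done <- px[id] >= x_end
    if (any(done)) {
      kd <- id[done]
      surv[kd] <- exp(-expo[kd])
      active[kd] <- FALSE
    }
  }
  # average sub-seed survivals back onto the rows
  surv_row <- colMeans(matrix(surv, q, length(rows)))
  list(rows = rows, col = je, surv = surv_row, open = surv_row > 0.5,
       x_entrance = grid$x[je])
}

#' Streamline capture thresholds at a gate
#'
#' Traces the electric-field lines (the carrier streamlines under
#' electroosmotic similitude) entering a gate from each transverse position
#' and records the maximum directional mobility-ratio threshold
#' `(grad(E^2) . s_hat) / |E|` met along the path through the gate (V/m2 at
#' the reference voltage). A particle with mobilities (`mu_ek`, `mu_dep<0`)
#' arriving on a streamline is blocked at applied voltage `V` once
#' `threshold * V / v_ref >= mu_ek / |mu_dep|`. The map depends only on
#' geometry and scales linearly with voltage, so one map serves a whole
#' sweep.
#'
#' @param field a [solve_potential()] solution.
#' @param readout_gate gate index to map.
#' @param n_substeps tracing refinement within the finest cells.
#' @return list with `rows` (grid row indices of the entrance plane), `col`
#'   (entrance column), `x_entrance`, `threshold` (V/m2 at `v_ref`), and
#'   `v_ref`.
#' @export
capture_threshold_map <- function(field, readout_gate, n_substeps = 2L) {
  grid <- field$grid; geo <- field$geometry
  p <- geo$gates$position[readout_gate]
  f <- gate_footprint(geo, readout_gate)
  x_e <- max(p - 1.15 * f, grid$x_lo)
  x_end <- min(p + 1.15 * f, grid$x_hi)
  je <- which.min(abs(grid$x - x_e))
  rows <- which(grid$mask[, je])

  ux <- field$Ex; uy <- field$Ey
  ux[!grid$mask] <- 0; uy[!grid$mask] <- 0
  # directional opposition ratio (V/m2): positive where E^2 grows along the
  # field line, i.e. where negative DEP opposes the carriage
  Em <- pmax(field$Emag, .Machine$double.eps)
  sp <- sqrt(ux^2 + uy^2); sp[sp == 0] <- NA
  rat <- (field$gradE2x * ux + field$gradE2y * uy) / sp / Em
  rat[!grid$mask | !is.finite(rat)] <- 0

  interp <- function(M, xs, ys) {
    jx <- pmin(pmax(findInterval(xs, grid$x), 1L), grid$nx - 1L)
    iy <- pmin(pmax(findInterval(ys, grid$y), 1L), grid$ny - 1L)
    tx <- pmin(pmax((xs - grid$x[jx]) / (grid$x[jx + 1L] - grid$x[jx]), 0), 1)
    ty <- pmin(pmax((ys - grid$y[iy]) / (grid$y[iy + 1L] - grid$y[iy]), 0), 1)
    M[cbind(iy, jx)] * (1 - tx) * (1 - ty) + M[cbind(iy, jx + 1L)] * tx * (1 - ty) +
      M[cbind(iy + 1L, jx)] * (1 - tx) * ty + M[cbind(iy + 1L, jx + 1L)] * tx * ty
  }
  n <- length(rows)
  px <- rep(grid$x[je], n); py <- grid$y[rows]
  thr <- pmax(interp(rat, px, py), 0)
  active <- rep(TRUE, n)
  maxit <- 12L * n_substeps * grid$nx
  for (it in seq_len(maxit)) {
    id <- which(active)
    if (!length(id)) break
    u1 <- interp(ux, px[id], py[id]); v1 <- interp(uy, px[id], py[id])
    s1 <- sqrt(u1^2 + v1^2)
    stalled <- s1 < 1e-12 * max(field$Emag, na.rm = TRUE)
    if (any(stalled)) {   # stagnation: treat as an infinite threshold
      thr[id[stalled]] <- Inf
      active[id[stalled]] <- FALSE
      id <- id[!stalled]; u1 <- u1[!stalled]; v1 <- v1[!stalled]; s1 <- s1[!stalled]
      if (!length(id)) next
    }
    ds <- 0.9 / n_substeps *
      grid$dx[pmin(pmax(findInterval(px[id], grid$xf), 1L), grid$nx)]
    mx <- px[id] + ds / 2 * u1 / s1; my <- py[id] + ds / 2 * v1 / s1
    u2 <- interp(ux, mx, my); v2 <- interp(uy, mx, my)
    s2 <- sqrt(u2^2 + v2^2); s2[s2 < 1e-300] <- 1e-300
    px[id] <- px[id] + ds * u2 / s2
    py[id] <- py[id] + ds * v2 / s2
    w <- channel_halfwidth(geo, px[id])
    py[id] <- pmin(pmax(py[id], -w * (1 - 1e-9)), w * (1 - 1e-9))
    thr[id] <- pmax(thr[id], interp(rat, px[id], py[id]))
    done <- px[id] >= x_end
    active[id[done]] <- FALSE
  }
  list(rows = rows, col = je, x_entrance = grid$x[je],
       threshold = thr, v_ref = field$applied_voltage)
}

# readout line: midway between the readout gate's wedge exit and the next
# gate's wedge entry (or a footprint past the last gate; near the outlet
# for a gate-free channel).
readout_position <- function(geo, k, grid = NULL) {
  if (geo$n_gates == 0L) {
    x <- if (!is.null(grid)) grid$x_hi - 2 * min(grid$dx) else
      0.95 * geo$channel_length
    return(x)
  }
  p <- geo$gates$position[k]; f <- gate_footprint(geo, k)
  if (k < geo$n_gates) {
    nxt <- geo$gates$position[k + 1L] - gate_footprint(geo, k + 1L)
    x <- (p + f + nxt) / 2
  } else {
    x <- p + 1.5 * f
  }
  if (!is.null(grid)) x <- min(max(x, grid$x_lo), grid$x_hi)
  x
}

#' Percent of particles passing the readout gate
#'
#' The ratio of the flux crossing the readout line to the unobstructed
#' reference influx, as a percentage clipped to \[0, 100\].
#'
#' @param solution a [solve_transport()] result.
#' @return numeric percentage in \[0, 100\].
#' @export
percent_passed <- function(solution) {
  if (solution$inlet_flux <= 0) stop("zero inlet flux")
  min(max(100 * solution$outlet_flux / solution$inlet_flux, 0), 100)
}

#' Rescale a field solution to a different applied voltage
#'
#' The Laplace problem is linear: the potential and field scale with the
#' applied voltage and `grad E^2` with its square, so a single reference
#' solve serves a whole voltage sweep.
#'
#' @param field a [solve_potential()] solution.
#' @param applied_voltage new total applied voltage (V).
#' @return a `gidep_field` identical to `field` but at the new voltage.
#' @export
scale_field <- function(field, applied_voltage) {
  s <- applied_voltage / field$applied_voltage
  field$phi <- field$phi * s
  field$phi_window <- field$phi_window * s
  field$Ex <- field$Ex * s; field$Ey <- field$Ey * s
  field$Emag <- field$Emag * s; field$E2 <- field$E2 * s^2
  field$gradE2x <- field$gradE2x * s^2; field$gradE2y <- field$gradE2y * s^2
  field$ekmr <- field$ekmr * s
  field$current <- field$current * s
  field$applied_voltage <- applied_voltage
  field
}

#' Predict the capture onset voltage from the mobility ratio
#'
#' Capture at the channel centreline sets in when the local ratio
#' `|grad E^2| / |E|` reaches the particle's electrokinetic mobility ratio
#' `mu_ek / |mu_dep|`. Because the centreline ratio scales linearly with the
#' applied voltage, one reference solve yields the onset voltage in closed
#' form.
#'
#' @param field a reference [solve_potential()] solution.
#' @param mu_ek electrokinetic mobility (m2 V-1 s-1).
#' @param mu_dep dielectrophoretic mobility (m4 V-2 s-1), non-zero.
#' @return onset voltage (V) for full centreline capture.
#' @export
predict_onset_voltage <- function(field, mu_ek, mu_dep) {
  if (mu_dep == 0) stop("mu_dep must be non-zero")
  peak <- max(ekmr_profile(field)$ekmr_Vpm2)
  # a uniform field has zero ratio up to discretization roundoff; compare
  # against the natural gradient scale E / channel length
  floor_scale <- max(field$Emag, na.rm = TRUE) /
    field$geometry$channel_length
  if (peak <= 1e-3 * floor_scale) {
    stop("uniform field: no gate gradient to capture at")
  }
  field$applied_voltage * (mu_ek / abs(mu_dep)) / peak
}

#' Percent passed from deterministic drift-streamline tracing
#'
#' Integrates massless drift trajectories `dx/ds = v/|v|`,
#' `v = u + mu_dep grad(E^2)`, from a flux-weighted seeding of the inlet
#' cross-section and reports the percentage of seeded flux that crosses the
#' readout line without entering the reversed-drift capture basin. This is
#' the geometric (diffusion-free) capture fraction: upstream gates focus
#' the drifting particles towards the centreline and the readout gate's
#' basin, growing from the insulator tips with voltage, intercepts an
#' increasing share of the flux. The published device transitions are
#' insensitive to the (deliberately inflated) model diffusivity, which this
#' readout reproduces by construction; [solve_transport()] provides the
#' diffusive concentration field for the same configuration.
#'
#' @param field a [solve_potential()] solution.
#' @param params a [physical_params()] object.
#' @param readout_gate as in [solve_transport()].
#' @param n_seeds number of streamline seeds across the inlet.
#' @param flow optional [flow_field()] result (similitude default).
#' @return percentage of inlet flux passing, in \[0, 100\].
#' @export
trace_passed <- function(field, params = field$params, readout_gate = NULL,
                         n_seeds = 400, flow = NULL) {
  grid <- field$grid; geo <- field$geometry
  if (is.null(flow)) flow <- flow_field(field, params, mode = "similitude")
  vx <- flow$ux + params$mu_dep * field$gradE2x
  vy <- flow$uy + params$mu_dep * field$gradE2y
  vx[!grid$mask] <- 0; vy[!grid$mask] <- 0
  if (is.null(readout_gate)) {
    readout_gate <- max(1L, geo$n_gates - 2L)
    if (!is.null(grid$window)) {
      readout_gate <- min(max(readout_gate, grid$window[1]), grid$window[2])
    }
  }
  x_rec <- readout_position(geo, readout_gate, grid)

  interp <- function(M, xs, ys) {
    jx <- pmin(pmax(findInterval(xs, grid$x), 1L), grid$nx - 1L)
    iy <- pmin(pmax(findInterval(ys, grid$y), 1L), grid$ny - 1L)
    tx <- pmin(pmax((xs - grid$x[jx]) / (grid$x[jx + 1L] - grid$x[jx]), 0), 1)
    ty <- pmin(pmax((ys - grid$y[iy]) / (grid$y[iy + 1L] - grid$y[iy]), 0), 1)
    M[cbind(iy, jx)] * (1 - tx) * (1 - ty) + M[cbind(iy, jx + 1L)] * tx * (1 - ty) +
      M[cbind(iy + 1L, jx)] * (1 - tx) * ty + M[cbind(iy + 1L, jx + 1L)] * tx * ty
  }
  h_min <- min(grid$dx)
  x0 <- grid$x_lo + 2 * h_min
  w0 <- channel_halfwidth(geo, x0)
  ys <- seq(-w0 * (1 - 1e-6), w0 * (1 - 1e-6), length.out = n_seeds)
  wgt <- pmax(interp(vx, rep(x0, n_seeds), ys), 0)
  px <- rep(x0, n_seeds); py <- ys
  alive <- rep(TRUE, n_seeds); passed <- rep(FALSE, n_seeds)
  # adaptive arc-length step: a fraction of the local cell size
  step_of <- function(xs) 0.9 * grid$dx[pmin(pmax(findInterval(xs, grid$xf) , 1L), grid$nx)]
  maxit <- 8L * grid$nx + 5000L
  for (it in seq_len(maxit)) {
    id <- which(alive)
    if (!length(id)) break
    ux <- interp(vx, px[id], py[id]); uy <- interp(vy, px[id], py[id])
    sp <- sqrt(ux^2 + uy^2)
    trapped <- ux < 0 | sp < 1e-12
    if (any(trapped)) {
      alive[id[trapped]] <- FALSE
      id <- id[!trapped]; ux <- ux[!trapped]; uy <- uy[!trapped]; sp <- sp[!trapped]
      if (!length(id)) next
    }
    ds <- step_of(px[id])
    mx <- px[id] + ds / 2 * ux / sp; my <- py[id] + ds / 2 * uy / sp
    ux2 <- interp(vx, mx, my); uy2 <- interp(vy, mx, my)
    sp2 <- sqrt(ux2^2 + uy2^2)
    tr2 <- ux2 < 0 | sp2 < 1e-12
    if (any(tr2)) {
      alive[id[tr2]] <- FALSE
      id <- id[!tr2]; ux2 <- ux2[!tr2]; uy2 <- uy2[!tr2]; sp2 <- sp2[!tr2]
      ds <- ds[!tr2]
      if (!length(id)) next
    }
    px[id] <- px[id] + ds * ux2 / sp2
    py[id] <- py[id] + ds * uy2 / sp2
    w <- channel_halfwidth(geo, px[id])
    py[id] <- pmin(pmax(py[id], -w * (1 - 1e-9)), w * (1 - 1e-9))
    done <- px[id] >= x_rec
    if (any(done)) {
      passed[id[done]] <- TRUE
      alive[id[done]] <- FALSE
    }
  }
  if (sum(wgt) <= 0) stop("zero inlet flux")
  100 * sum(wgt[passed]) / sum(wgt)
}

#' Langevin particle-tracking cross-check of the capture model
#'
#' Tracks `n_particles` overdamped-Langevin particles
#' (`dx = v dt + sqrt(2 D dt) xi`) through the solved field with reflective
#' walls and an absorbing readout line, and returns the flux-weighted
#' percentage reaching the line before the step budget runs out. Serves as
#' an independent stochastic oracle for [solve_transport()].
#'
#' @param field a [solve_potential()] solution.
#' @param params a [physical_params()] object.
#' @param n_particles number of particles (>= 1000 for a stable estimate).
#' @param seed integer RNG seed; identical seeds give identical results.
#' @param flow optional [flow_field()] result (similitude default).
#' @param readout_gate as in [solve_transport()].
#' @param max_steps step budget per particle.
#' @return list with `percent_passed`, `n_passed`, `n_particles`, `dt`,
#'   `steps_used`.
#' @export
particle_tracking_oracle <- function(field, params = field$params,
                                     n_particles = 10000, seed = 1L,
                                     flow = NULL, readout_gate = NULL,
                                     max_steps = 200000L) {
  stopifnot(n_particles >= 1)
  grid <- field$grid
  geo <- field$geometry
  D <- params$diffusion_coefficient
  if (is.null(flow)) flow <- flow_field(field, params, mode = "similitude")
  vx <- flow$ux + params$mu_dep * field$gradE2x
  vy <- flow$uy + params$mu_dep * field$gradE2y
  vx[!grid$mask] <- 0; vy[!grid$mask] <- 0
  if (is.null(readout_gate)) {
    readout_gate <- max(1L, geo$n_gates - 2L)
    if (!is.null(grid$window)) {
      readout_gate <- min(max(readout_gate, grid$window[1]), grid$window[2])
    }
  }
  x_rec <- readout_position(geo, readout_gate, grid)

  h_min <- min(min(grid$dx), min(grid$dy))
  vmax <- max(sqrt(vx^2 + vy^2))
  dt <- 0.25 * h_min / max(vmax, .Machine$double.eps)
  if (vmax * dt / h_min > 0.5) stop("time step violates the advective CFL limit")

  set.seed(seed)
  # release particles on the inlet line, flux-weighted over the cross-section
  x0 <- grid$x_lo + 2 * h_min
  iy <- which(grid$mask[, 2])
  wgt <- pmax(vx[cbind(iy, 2L)], 0) * grid$dy[iy]
  iy_draw <- sample(iy, n_particles, replace = TRUE, prob = wgt / sum(wgt))
  px <- rep(x0, n_particles)
  py <- grid$y[iy_draw] + (stats::runif(n_particles) - 0.5) * grid$dy[iy_draw]

  interp <- function(M, xs, ys) {
    jx <- pmin(pmax(findInterval(xs, grid$x), 1L), grid$nx - 1L)
    iy2 <- pmin(pmax(findInterval(ys, grid$y), 1L), grid$ny - 1L)
    tx <- pmin(pmax((xs - grid$x[jx]) / (grid$x[jx + 1L] - grid$x[jx]), 0), 1)
    ty <- pmin(pmax((ys - grid$y[iy2]) / (grid$y[iy2 + 1L] - grid$y[iy2]), 0), 1)
    M[cbind(iy2, jx)] * (1 - tx) * (1 - ty) + M[cbind(iy2, jx + 1L)] * tx * (1 - ty) +
      M[cbind(iy2 + 1L, jx)] * (1 - tx) * ty + M[cbind(iy2 + 1L, jx + 1L)] * tx * ty
  }

  alive <- rep(TRUE, n_particles)
  passed <- rep(FALSE, n_particles)
  sq <- sqrt(2 * D * dt)
  steps <- 0L
  while (any(alive) && steps < max_steps) {
    steps <- steps + 1L
    id <- which(alive)
    ux <- interp(vx, px[id], py[id])
    uy <- interp(vy, px[id], py[id])
    # entering the reversed-drift basin means capture at the tips; the
    # basin is the same cell set the PDE formulation absorbs on
    jc <- pmin(pmax(findInterval(px[id], grid$xf), 1L), grid$nx)
    ic <- pmin(pmax(findInterval(py[id], grid$yf), 1L), grid$ny)
    trapped <- vx[cbind(ic, jc)] < 0
    if (any(trapped)) {
      alive[id[trapped]] <- FALSE
      id <- id[!trapped]
      if (!length(id)) next
      ux <- ux[!trapped]; uy <- uy[!trapped]
    }
    nxp <- px[id] + ux * dt + sq * stats::rnorm(length(id))
    nyp <- py[id] + uy * dt + sq * stats::rnorm(length(id))
    # reflect at inlet plane and walls
    nxp <- ifelse(nxp < grid$x_lo, 2 * grid$x_lo - nxp, nxp)
    w <- channel_halfwidth(geo, nxp)
    over <- abs(nyp) > w
    nyp[over] <- sign(nyp[over]) * pmax(2 * w[over] - abs(nyp[over]), 0)
    still <- abs(nyp) > w
    nyp[still] <- sign(nyp[still]) * w[still] * 0.999
    px[id] <- nxp; py[id] <- nyp
    done <- nxp >= x_rec
    passed[id[done]] <- TRUE
    alive[id[done]] <- FALSE
  }
  list(percent_passed = 100 * sum(passed) / n_particles,
       n_passed = sum(passed), n_particles = n_particles,
       dt = dt, steps_used = steps)
}

#' @export
print.gidep_transport <- function(x, ...) {
  cat(sprintf("gidep transport solution: %s at %.4g V, mu_DEP %.3g\n",
              x$field$geometry$name, x$field$applied_voltage, x$params$mu_dep))
  cat(sprintf("  percent passed at readout gate %d: %.2f%%\n",
              x$readout_gate, x$percent_passed))
  cat(sprintf("  max cell Peclet %.3g, c range [%.3g, %.3g]\n",
              x$max_cell_peclet, x$min_concentration, x$max_concentration))
  invisible(x)
}
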