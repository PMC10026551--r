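#' Phantom geometry
#'
#' Geometry of the agarose-gel cylinder with an axially centered copper-wire
#' heat source, discretized on an axisymmetric (r, z) grid. Defaults describe
#' a 1 ml gel tube (radius 4.5 mm, height chosen to give 1 ml) with a 1 mm x
#' 4.52 mm wire and the fiber-optic probe 1.3 mm from the wire surface.
#'
#' @param gel_radius gel cylinder radius, m.
#' @param gel_height gel cylinder height, m; default derived from 1 ml.
#' @param wire_radius heat-source wire radius, m.
#' @param wire_length wire length, m.
#' @param probe_offset radial distance from the wire surface to the probe, m.
#' @param grid_nr,grid_nz radial and axial cell counts.
#' @return A `phantom_geometry` object.
#' @export
phantom_geometry <- function(gel_radius = 4.5e-3,
                             gel_height = 1e-6 / (pi * 4.5e-3^2),
                             wire_radius = 1e-3, wire_length = 4.52e-3,
                             probe_offset = 1.3e-3,
                             grid_nr = 24, grid_nz = 48) {
  stopifnot(wire_radius < gel_radius, wire_length < gel_height,
            wire_radius + probe_offset < gel_radius,
            grid_nr >= 4, grid_nz >= 4)
  if (gel_radius / grid_nr > wire_radius / 4) {
    stop("grid too coarse: need at least 4 radial cells across the wire radius")
  }
  structure(list(gel_radius = gel_radius, gel_height = gel_height,
                 wire_radius = wire_radius, wire_length = wire_length,
                 probe_offset = probe_offset,
                 grid_nr = as.integer(grid_nr), grid_nz = as.integer(grid_nz)),
            class = "phantom_geometry")
}

#' Material and boundary properties
#'
#' Thermal properties of the 1% agarose gel and standard copper values for
#' the wire, plus the convective surface boundary (the tube is suspended in
#' air; conduction to the holder is neglected).
#'
#' @param rho_gel gel density, kg/m^3.
#' @param cp_gel gel specific heat, J/(kg K).
#' @param k_gel gel thermal conductivity, W/(m K).
#' @param sigma_gel gel electrical conductivity, S/m (carried for
#'   completeness; the calibrated wire source does not use it).
#' @param h_conv convective heat-transfer coefficient, W/(m^2 K).
#' @param T_inf ambient temperature, degrees Celsius.
#' @param rho_wire,cp_wire,k_wire copper wire properties.
#' @return A `material_props` object.
#' @export
material_props <- function(rho_gel = 960, cp_gel = 3900, k_gel = 0.566,
                           sigma_gel = 2.1, h_conv = 21, T_inf = 21.1,
                           rho_wire = 8960, cp_wire = 385, k_wire = 400) {
  stopifnot(rho_gel > 0, cp_gel > 0, k_gel > 0, sigma_gel > 0, h_conv >= 0,
            rho_wire > 0, cp_wire > 0, k_wire > 0)
  structure(list(rho_gel = rho_gel, cp_gel = cp_gel, k_gel = k_gel,
                 sigma_gel = sigma_gel, h_conv = h_conv, T_inf = T_inf,
                 rho_wire = rho_wire, cp_wire = cp_wire, k_wire = k_wire),
            class = "material_props")
}

#' Alternating-magnetic-field drive
#'
#' @param H_amplitude field amplitude, kA/m peak; a scalar, a vector (one
#'   value per simulation step) or a function of time (s).
#' @param frequency field frequency, kHz (informational; 160 by default).
#' @param H_max maximum field amplitude, kA/m peak.
#' @return A `field_drive` object.
#' @export
field_drive <- function(H_amplitude, frequency = 160, H_max = 9.8) {
  if (is.numeric(H_amplitude)) {
    stopifnot(all(H_amplitude >= 0), all(H_amplitude <= H_max + 1e-9))
  }
  structure(list(H_amplitude = H_amplitude, frequency = frequency,
                 H_max = H_max),
            class = "field_drive")
}

#' Oersted to kA/m conversion
#'
#' 1 Oe = 79.5775 A/m.
#'
#' @param H field strength in oersted (>= 0).
#' @return Field strength in kA/m.
#' @examples
#' oe_to_kam(123) # 9.788 kA/m
#' @export
oe_to_kam <- function(H) {
  stopifnot(all(H >= 0))
  H * 0.0795775
}

# --- finite-volume machinery -------------------------------------------------

# Assemble the axisymmetric finite-volume system on cell centers
# r_i = (i - 1/2) dr, z_j = (j - 1/2) dz. Returns the heat-capacity vector
# M (J/K per cell), the conduction + boundary stiffness matrix K (W/K,
# symmetric, flux form so that row sums equal the boundary conductances),
# the boundary conductance vector Gb (W/K), the wire-cell volume vector
# (m^3, zero outside the wire), and the probe interpolation weights.
thermal_system <- function(geom, props) {
  nr <- geom$grid_nr; nz <- geom$grid_nz
  dr <- geom$gel_radius / nr; dz <- geom$gel_height / nz
  r <- (seq_len(nr) - 0.5) * dr
  z <- (seq_len(nz) - 0.5) * dz
  id <- function(i, j) i + (j - 1L) * nr

  # partial-volume (cut-cell) wire fractions: the discrete wire volume is
  # exact on every grid, so the source power does not staircase under
  # refinement; material properties are volume-blended in cut cells
  rlo <- (seq_len(nr) - 1L) * dr; rhi <- seq_len(nr) * dr
  fr <- (pmin(rhi, geom$wire_radius)^2 - pmin(rlo, geom$wire_radius)^2) /
    (rhi^2 - rlo^2)
  zlo <- (seq_len(nz) - 1L) * dz; zhi <- seq_len(nz) * dz
  w_lo <- (geom$gel_height - geom$wire_length) / 2
  w_hi <- (geom$gel_height + geom$wire_length) / 2
  fz <- pmax(0, pmin(zhi, w_hi) - pmax(zlo, w_lo)) / dz
  frac <- outer(fr, fz)
  kcell <- props$k_gel + (props$k_wire - props$k_gel) * frac
  rhoCp <- props$rho_gel * props$cp_gel +
    (props$rho_wire * props$cp_wire - props$rho_gel * props$cp_gel) * frac
  vol <- outer(2 * pi * r * dr, rep(dz, nz)) # cell volumes

  n <- nr * nz
  harm <- function(k1, k2) 2 * k1 * k2 / (k1 + k2)
  # radial faces between (i, j) and (i+1, j): area 2*pi*(i*dr)*dz
  ir <- seq_len(nr - 1L)
  Gr <- harm(kcell[ir, , drop = FALSE], kcell[ir + 1L, , drop = FALSE]) *
    outer(2 * pi * ir * dr * dz / dr, rep(1, nz))
  ar <- as.vector(outer(ir, (seq_len(nz) - 1L) * nr, `+`))
  # axial faces between (i, j) and (i, j+1): area 2*pi*r_i*dr
  jz <- seq_len(nz - 1L)
  Gz <- harm(kcell[, jz, drop = FALSE], kcell[, jz + 1L, drop = FALSE]) *
    outer(2 * pi * r * dr / dz, rep(1, nz - 1L))
  az <- as.vector(outer(seq_len(nr), (jz - 1L) * nr, `+`))
  a <- c(ar, az); b <- c(ar + 1L, az + nr); G <- c(Gr, Gz)
  Koff <- Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = c(-G, -G),
                               dims = c(n, n))
  # convective boundary: series half-cell conduction + surface film
  Gb <- numeric(n)
  if (props$h_conv > 0) {
    side <- id(nr, seq_len(nz))
    Gb[side] <- Gb[side] + (2 * pi * geom$gel_radius * dz) /
      (1 / props$h_conv + (dr / 2) / kcell[nr, ])
    caps_A <- 2 * pi * r * dr
    bot <- id(seq_len(nr), 1L); top <- id(seq_len(nr), nz)
    Gb[bot] <- Gb[bot] + caps_A / (1 / props$h_conv + (dz / 2) / kcell[, 1L])
    Gb[top] <- Gb[top] + caps_A / (1 / props$h_conv + (dz / 2) / kcell[, nz])
  }
  K <- Koff + Matrix::Diagonal(x = -Matrix::rowSums(Koff) + Gb)

  # probe: bilinear interpolation at (wire surface + offset, mid-height)
  rp <- geom$wire_radius + geom$probe_offset
  zp <- geom$gel_height / 2
  i0 <- min(max(findInterval(rp, r), 1L), nr - 1L)
  j0 <- min(max(findInterval(zp, z), 1L), nz - 1L)
  wr <- (rp - r[i0]) / dr; wz <- (zp - z[j0]) / dz
  wr <- min(max(wr, 0), 1); wz <- min(max(wz, 0), 1)
  probe <- list(idx = c(id(i0, j0), id(i0 + 1L, j0),
                        id(i0, j0 + 1L), id(i0 + 1L, j0 + 1L)),
                w = c((1 - wr) * (1 - wz), wr * (1 - wz),
                      (1 - wr) * wz, wr * wz))

  list(nr = nr, nz = nz, r = r, z = z,
       M = as.vector(rhoCp * vol), K = K, Gb = Gb,
       wire_vol = as.vector(vol * frac), probe = probe)
}

probe_temp <- function(sys, Tvec) sum(sys$probe$w * Tvec[sys$probe$idx])

steady_field <- function(sys, q, T_inf) {
  if (all(sys$Gb == 0)) stop("steady state undefined with h_conv = 0 (no heat path out)")
  rhs <- q + sys$Gb * T_inf
  as.vector(Matrix::solve(sys$K, rhs))
}

#' Calibrated volumetric heat source
#'
#' The eddy-current power deposited in the wire is modeled as a uniform
#' volumetric source `Q = c_sar * H^2` (W/m^3 with H in kA/m), the standard
#' quadratic field dependence of induction heating at fixed frequency.
#'
#' @param c_sar calibration constant, W/(m^3 (kA/m)^2); > 0.
#' @param H_ref the reference amplitude the constant was calibrated at, kA/m.
#' @return A `sar_model` object.
#' @export
sar_model <- function(c_sar, H_ref = 9.78) {
  stopifnot(c_sar > 0, H_ref > 0)
  structure(list(c_sar = c_sar, H_ref = H_ref), class = "sar_model")
}

#' Calibrate the wire source against a known steady temperature rise
#'
#' Finds `c_sar` such that the steady-state probe temperature rise under a
#' constant field `H_ref` equals `target_dT`. The conduction problem is
#' linear in the source, so one trial steady solve plus scaling is exact.
#'
#' @param geom a [phantom_geometry()].
#' @param props a [material_props()].
#' @param target_dT target steady probe temperature rise, kelvin.
#' @param H_ref calibration field amplitude, kA/m peak.
#' @return A [sar_model()].
#' @examples
#' \donttest{
#' sar <- calibrate_sar(phantom_geometry(), material_props(), 23, 9.78)
#' }
#' @export
calibrate_sar <- function(geom, props, target_dT = 23, H_ref = 9.78) {
  stopifnot(target_dT > 0)
  sys <- thermal_system(geom, props)
  q1 <- H_ref^2 * sys$wire_vol # c_sar = 1 trial
  Tss <- steady_field(sys, q1, props$T_inf)
  dT1 <- probe_temp(sys, Tss) - props$T_inf
  if (!is.finite(dT1) || dT1 <= 0) stop("trial steady solve did not converge to a heated state")
  sar_model(target_dT / dT1, H_ref)
}

#' Forward thermal simulation of the phantom
#'
#' Integrates the axisymmetric heat equation
#' `rho Cp dT/dt = div(k grad T) + Q_SAR` on the finite-volume grid with the
#' calibrated wire source and convective surface loss, starting from a
#' uniform field at `T_inf`. The default implicit (backward Euler) scheme is
#' unconditionally stable; the explicit scheme refuses configurations that
#' violate its stability limit.
#'
#' @param geom a [phantom_geometry()].
#' @param props a [material_props()].
#' @param drive a [field_drive()]; amplitude may be scalar, per-step vector,
#'   or a function of time.
#' @param sar a [sar_model()] from [calibrate_sar()].
#' @param dt time step, s.
#' @param duration simulated time, s.
#' @param scheme `"implicit"` (default) or `"explicit"`.
#' @param snapshot_times optional times (s) at which to record the full
#'   temperature field.
#' @return A [temperature_trace()] of the probe temperature, with attributes
#'   `energy_J` (total thermal energy relative to ambient, per sample),
#'   `power_W` (discrete source power per step) and, if requested,
#'   `snapshots` (named list of nr x nz matrices).
#' @export
simulate_thermal <- function(geom, props, drive, sar, dt = 0.1, duration,
                             scheme = c("implicit", "explicit"),
                             snapshot_times = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(drive, "field_drive"), inherits(sar, "sar_model"),
            dt > 0, duration >= dt)
  sys <- thermal_system(geom, props)
  nstep <- ceiling(duration / dt)
  H <- drive$H_amplitude
  Hseq <- if (is.function(H)) H((seq_len(nstep) - 1) * dt)
          else if (length(H) == 1L) rep(H, nstep)
          else if (length(H) >= nstep) H[seq_len(nstep)]
          else stop("per-step H vector shorter than the number of steps")

  n <- length(sys$M)
  if (scheme == "explicit") {
    dt_max <- min(sys$M / Matrix::diag(sys$K))
    if (dt > dt_max) {
      stop(sprintf(
        "explicit scheme unstable: dt = %g s exceeds the stability limit %.3g s; reduce dt or use the implicit scheme",
        dt, dt_max))
    }
  } else {
    A <- Matrix::Diagonal(x = sys$M / dt) + sys$K
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(A))
  }

  Tvec <- rep(props$T_inf, n)
  Tp <- numeric(nstep + 1); Tp[1] <- probe_temp(sys, Tvec)
  energy <- numeric(nstep + 1)
  power <- numeric(nstep)
  snaps <- list()
  snap_steps <- if (is.null(snapshot_times)) integer(0) else
    pmin(pmax(round(snapshot_times / dt), 1L), nstep)

  bT <- sys$Gb * props$T_inf
  for (k in seq_len(nstep)) {
    q <- (sar$c_sar * Hseq[k]^2) * sys$wire_vol
    power[k] <- sum(q)
    if (scheme == "implicit") {
      rhs <- sys$M / dt * Tvec + q + bT
      Tvec <- as.vector(Matrix::solve(ch, rhs))
    } else {
      flux <- as.vector(sys$K %*% Tvec) - bT
      Tvec <- Tvec + dt / sys$M * (q - flux)
    }
    Tp[k + 1] <- probe_temp(sys, Tvec)
    energy[k + 1] <- sum(sys$M * (Tvec - props$T_inf))
    if (k %in% snap_steps) {
      snaps[[sprintf("t=%gs", k * dt)]] <- matrix(Tvec, sys$nr, sys$nz)
    }
  }
  out <- temperature_trace(seq(0, nstep * dt, by = dt), Tp)
  attr(out, "energy_J") <- energy
  attr(out, "power_W") <- power
  if (length(snaps)) attr(out, "snapshots") <- snaps
  out
}

#' Open-loop field pulse experiment
#'
#' Heats with a constant field for `pulse_s` seconds, then records free
#' cooling; the trace spans at least three pulse lengths.
#'
#' @inheritParams simulate_thermal
#' @param amplitude pulse field amplitude, kA/m peak.
#' @param pulse_s pulse duration, s.
#' @param duration total trace length, s (default `3 * pulse_s`).
#' @return A [temperature_trace()].
#' @export
open_loop_pulse <- function(geom, props, amplitude, pulse_s = 30, sar,
                            dt = 0.1, duration = 3 * pulse_s) {
  stopifnot(duration >= 3 * pulse_s)
  drive <- field_drive(function(t) ifelse(t < pulse_s, amplitude, 0),
                       H_max = max(amplitude, 9.8))
  simulate_thermal(geom, props, drive, sar, dt = dt, duration = duration)
}

#' Grid-convergence study
#'
#' Re-runs the same continuous problem on successively refined grids and
#' reports the probe temperature at a fixed evaluation time together with
#' the relative change between consecutive levels. Levels whose change from
#' the previous level exceeds 5% are flagged as unconverged.
#'
#' @inheritParams simulate_thermal
#' @param refine numeric multipliers applied to the base grid counts, in
#'   increasing order; at least 3 levels.
#' @param eval_time evaluation time, s.
#' @return Data frame with `level`, `nr`, `nz`, `T_probe_C`, `rel_change`,
#'   `converged`.
#' @export
grid_convergence_study <- function(geom, props, drive, sar,
                                   refine = c(1, 1.5, 2), eval_time = 600,
                                   dt = 0.5) {
  stopifnot(length(refine) >= 3, all(diff(refine) > 0))
  res <- lapply(refine, function(f) {
    g <- phantom_geometry(gel_radius = geom$gel_radius,
                          gel_height = geom$gel_height,
                          wire_radius = geom$wire_radius,
                          wire_length = geom$wire_length,
                          probe_offset = geom$probe_offset,
                          grid_nr = max(4L, round(geom$grid_nr * f)),
                          grid_nz = max(4L, round(geom$grid_nz * f)))
    tr <- simulate_thermal(g, props, drive, sar, dt = dt, duration = eval_time)
    c(nr = g$grid_nr, nz = g$grid_nz, T = tr$T_probe_C[nrow(tr)])
  })
  Tp <- vapply(res, `[[`, numeric(1), "T")
  rel <- c(NA, abs(diff(Tp)) / abs(Tp[-length(Tp)] - props$T_inf))
  data.frame(level = seq_along(refine),
             nr = vapply(res, `[[`, numeric(1), "nr"),
             nz = vapply(res, `[[`, numeric(1), "nz"),
             T_probe_C = Tp,
             rel_change = rel,
             converged = is.na(rel) | rel < 0.05)
}

#' Steady-state probe temperature rise
#'
#' Direct steady conduction solve; the workhorse of the sensitivity
#' surrogate. The rise scales exactly as `(H / H_ref)^2`.
#'
#' @inheritParams simulate_thermal
#' @param H field amplitude, kA/m peak.
#' @param probe_offset optional probe offset override, m.
#' @return Probe temperature rise above ambient, kelvin.
#' @export
steady_probe_dT <- function(geom, props, sar, H, probe_offset = NULL) {
  if (!is.null(probe_offset)) {
    geom <- phantom_geometry(gel_radius = geom$gel_radius,
                             gel_height = geom$gel_height,
                             wire_radius = geom$wire_radius,
                             wire_length = geom$wire_length,
                             probe_offset = probe_offset,
                             grid_nr = geom$grid_nr, grid_nz = geom$grid_nz)
  }
  sys <- thermal_system(geom, props)
  q <- (sar$c_sar * H^2) * sys$wire_vol
  Tss <- steady_field(sys, q, props$T_inf)
  probe_temp(sys, Tss) - props$T_inf
}
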