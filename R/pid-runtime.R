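#' Closed-loop controller configuration
#'
#' Collects everything the discrete loop needs: PID gains, set point,
#' control interval (100 ms by default, matching the sensor averaging
#' interval), actuator voltage bounds, safety thresholds, and the RC
#' rate-limiter time constant. In `"volts"` mode the controller output lives
#' in the 0.25--1.25 V supply range mapped linearly to 4.2--9.8 kA/m; in
#' `"normalized"` mode the output is a dimensionless command in \[0, 1\]
#' scaled by the maximum field.
#'
#' @param gains a [pid_gains()].
#' @param setpoint target temperature, degrees Celsius.
#' @param dt control interval, seconds.
#' @param mode `"volts"` or `"normalized"`.
#' @param u_min,u_max actuator bounds; defaults 0.25/1.25 V in volts mode,
#'   0/1 in normalized mode.
#' @param thresholds named numeric vector of safety thresholds, degrees
#'   Celsius, one per monitored probe (e.g. `c(probe = 25)`); empty to
#'   disable the gate.
#' @param rc_tau RC rate-limiter time constant, seconds.
#' @param rc_enabled apply the RC limiter between controller and actuator.
#' @param dvdt_max supply slew-rate fault bound, V/s (informational).
#' @param hysteresis gate release band, kelvin (0 = strict relay).
#' @return A `controller_config` object.
#' @export
controller_config <- function(gains, setpoint, dt = 0.1,
                              mode = c("volts", "normalized"),
                              u_min = NULL, u_max = NULL,
                              thresholds = c(probe = 50),
                              rc_tau = 0.2, rc_enabled = TRUE,
                              dvdt_max = 5, hysteresis = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(gains, "pid_gains"), dt > 0, rc_tau > 0, hysteresis >= 0)
  if (is.null(u_min)) u_min <- if (mode == "volts") 0.25 else 0
  if (is.null(u_max)) u_max <- if (mode == "volts") 1.25 else 1
  stopifnot(u_min < u_max)
  if (length(thresholds) && is.null(names(thresholds))) {
    stop("thresholds must be a named vector (probe id -> threshold degC)")
  }
  structure(list(gains = gains, setpoint = setpoint, dt = dt, mode = mode,
                 u_min = u_min, u_max = u_max, thresholds = thresholds,
                 rc_tau = rc_tau, rc_enabled = rc_enabled,
                 dvdt_max = dvdt_max, hysteresis = hysteresis),
            class = "controller_config")
}

#' Initial controller state
#'
#' The integral accumulator is pre-loaded so that the output starts exactly
#' at a chosen resting value (bumpless start): `integral = u0 / Ki`. The
#' default rests at the actuator floor or at zero, whichever is closer to
#' zero, so a wide symmetric actuator range still starts from a quiescent
#' controller.
#'
#' @param cfg a [controller_config()].
#' @param u0 initial resting output, volts.
#' @return A `control_state` list.
#' @export
control_state <- function(cfg, u0 = max(cfg$u_min, 0)) {
  structure(list(
    integral = if (cfg$gains$ki > 0) u0 / cfg$gains$ki else 0,
    prev_error = 0, filtered_derivative = 0,
    u = u0, gated = FALSE),
    class = "control_state")
}

#' One discrete PID update
#'
#' Backward-Euler integral with clamping anti-windup (the accumulator is
#' frozen while the output is saturated in the direction the error pushes),
#' derivative of the error through a first-order filter with constant
#' `tau_d`, and output clamped to the actuator bounds. Always returns a
#' bounded output.
#'
#' @param state a `control_state` (see [control_state()]).
#' @param T_meas measured temperature, degrees Celsius.
#' @param cfg a [controller_config()].
#' @param freeze_integral hold the accumulator (used while the safety gate
#'   is closed).
#' @return The updated state; the commanded output is `state$u`.
#' @export
pid_step <- function(state, T_meas, cfg, freeze_integral = FALSE) {
  g <- cfg$gains; dt <- cfg$dt
  e <- cfg$setpoint - T_meas
  de <- if (is.na(state$prev_error)) 0 else e - state$prev_error
  dfilt <- (g$tau_d * state$filtered_derivative + de) / (g$tau_d + dt)

  int_new <- state$integral + e * dt
  u_raw <- g$kp * e + g$ki * int_new + g$kd * dfilt
  commit <- !freeze_integral &&
    !(u_raw > cfg$u_max && e > 0) && !(u_raw < cfg$u_min && e < 0)
  if (commit) state$integral <- int_new
  u_raw <- g$kp * e + g$ki * state$integral + g$kd * dfilt

  state$prev_error <- e
  state$filtered_derivative <- dfilt
  state$u <- min(max(u_raw, cfg$u_min), cfg$u_max)
  state
}

#' Control voltage to field amplitude
#'
#' In `"volts"` mode the map is piecewise linear through the measured
#' anchors: 0 V is supply-off (0 kA/m), 0.25 V gives 4.2 kA/m, 1.25 V gives
#' 9.8 kA/m, clamped above. In `"normalized"` mode `H = u * H_max` with `u`
#' clamped to \[0, 1\].
#'
#' @param u control voltage (or normalized command).
#' @param cfg a [controller_config()] (only `mode` is used).
#' @param drive a [field_drive()] supplying `H_max`.
#' @return Field amplitude, kA/m peak.
#' @export
actuator_map <- function(u, cfg, drive = field_drive(0)) {
  if (cfg$mode == "normalized") {
    return(pmin(pmax(u, 0), 1) * drive$H_max)
  }
  lo_u <- 0.25; lo_H <- 4.2; hi_u <- 1.25; hi_H <- 9.8
  u <- pmin(pmax(u, 0), hi_u)
  ifelse(u <= lo_u,
         u / lo_u * lo_H,
         lo_H + (u - lo_u) * (hi_H - lo_H) / (hi_u - lo_u))
}

#' First-order RC rate limiter
#'
#' Exact per-step discretization of `tau y' = u - y`. For a step of
#' amplitude `A` the worst-case output slope is `A (1 - exp(-dt/tau)) / dt`,
#' which approaches `A / tau` as `dt -> 0` -- hence a 0.25 to 1.25 V step
#' through `tau = 0.2 s` slews at most 5 V/s.
#'
#' @param u input series, volts.
#' @param rc_tau time constant, seconds.
#' @param dt sampling interval, seconds; should satisfy `dt < rc_tau / 2`.
#' @param y0 initial output (defaults to `u[1]`).
#' @return Smoothed series of the same length.
#' @export
rc_limit <- function(u, rc_tau, dt, y0 = u[1]) {
  stopifnot(rc_tau > 0, dt > 0)
  if (dt >= rc_tau / 2) {
    warning("dt >= rc_tau/2: RC limiter poorly resolved at this sampling rate")
  }
  a <- 1 - exp(-dt / rc_tau)
  y <- numeric(length(u))
  prev <- y0
  for (k in seq_along(u)) {
    prev <- prev + a * (u[k] - prev)
    y[k] <- prev
  }
  y
}

#' Safety threshold gate
#'
#' Forces the commanded output to zero whenever any monitored probe exceeds
#' its threshold (strict comparison; optional hysteresis delays release).
#' The gate has priority over the PID law. A missing (`NA`) probe reading is
#' treated as a fault and closes the gate (fail-safe).
#'
#' @param T_probes named numeric vector of probe readings, degrees Celsius.
#' @param thresholds named numeric vector of thresholds; names must match
#'   probe ids.
#' @param u commanded output before gating.
#' @param gated current gate state.
#' @param hysteresis release band, kelvin.
#' @return List with `u` (0 if gated), `gated`, and `tripped` (character
#'   vector of probe ids above threshold or missing).
#' @export
safety_gate <- function(T_probes, thresholds, u, gated = FALSE,
                        hysteresis = 0) {
  if (!length(thresholds)) return(list(u = u, gated = FALSE, tripped = character(0)))
  readings <- T_probes[names(thresholds)]
  missing <- is.na(readings)
  over <- missing | readings > thresholds
  below <- !missing & readings < thresholds - hysteresis
  gated_new <- if (gated) !all(below) else any(over)
  list(u = if (gated_new) 0 else u,
       gated = gated_new,
       tripped = names(thresholds)[over])
}

#' Thermal dose parameters
#'
#' Sapareto--Dewey cumulative-equivalent-minutes convention: per-degree base
#' `R = 0.5` at or above the 43 degC breakpoint and `R = 0.25` below it.
#'
#' @param r_above,r_below per-degree isoeffect ratios.
#' @param breakpoint breakpoint temperature, degrees Celsius.
#' @return A `dose_params` list.
#' @export
dose_params <- function(r_above = 0.5, r_below = 0.25, breakpoint = 43) {
  stopifnot(r_above > 0, r_below > 0)
  structure(list(r_above = r_above, r_below = r_below,
                 breakpoint = breakpoint), class = "dose_params")
}

#' Cumulative equivalent minutes at 43 degC
#'
#' `CEM43 = sum dt_min * R^(43 - T_i)` over the sampling intervals of the
#' trace (right-endpoint temperatures, so doses of concatenated segments add
#' exactly). Accepts a [temperature_trace()] or a numeric temperature vector
#' with an explicit interval `dt` (then every element counts as one
#' interval).
#'
#' @param trace a [temperature_trace()] or numeric vector of temperatures
#'   (degrees Celsius).
#' @param params a [dose_params()].
#' @param dt sampling interval in seconds; required for numeric input.
#' @return Dose in equivalent minutes at 43 degC.
#' @examples
#' cem43(rep(45, 900), dt = 1) # 15 min at 45 degC -> 60 min
#' @export
cem43 <- function(trace, params = dose_params(), dt = NULL) {
  if (inherits(trace, "temperature_trace")) {
    temps <- trace$T_probe_C[-1]
    dt <- trace_dt(trace)
  } else {
    if (is.null(dt)) stop("dt required for a plain temperature vector")
    temps <- trace
  }
  R <- ifelse(temps >= params$breakpoint, params$r_above, params$r_below)
  sum(dt / 60 * R^(params$breakpoint - temps))
}

#' Run the discrete closed loop
#'
#' Executes the full control loop at interval `dt`: read the (optionally
#' noisy) probe temperature, apply the safety gate, compute the PID command,
#' pass it through the RC rate limiter, map to field amplitude, advance the
#' plant, and accumulate thermal dose. The plant is either a two-lag LTI
#' model ([plant_params()]) or the finite-volume phantom (a list with
#' `geom`, `props`, `sar`).
#'
#' The logged `u_V` column is the commanded output after the gate (zero
#' within the same control step whenever a threshold is exceeded);
#' `H_kA_per_m` is the physical field after the RC limiter and actuator map.
#'
#' @param plant a [plant_params()] or `list(geom=, props=, sar=)`.
#' @param cfg a [controller_config()].
#' @param duration run length, seconds.
#' @param baseline initial temperature, degrees Celsius (LTI mode; thermal
#'   mode starts at `props$T_inf`).
#' @param drive a [field_drive()] supplying `H_max` for the actuator map.
#' @param noise optional measurement noise: `list(sd = <kelvin>)`, one
#'   Gaussian draw per control sample; requires `seed`.
#' @param seed RNG seed, required when `noise` is given.
#' @return A `closed_loop_run`: list with `trace` (a [temperature_trace()]
#'   with columns `u_V`, `H_kA_per_m`, `gated`, `cem43_min`), `events`
#'   (safety event log), `dose` (final CEM43, minutes), and `metrics`
#'   (from [transient_metrics()], when the set point is above baseline).
#' @export
run_closed_loop <- function(plant, cfg, duration, baseline = 21.1,
                            drive = field_drive(0, H_max = 9.8),
                            noise = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "controller_config"), duration > cfg$dt)
  if (!is.null(noise)) {
    if (is.null(seed)) stop("seed required when a noise model is attached")
    set.seed(seed)
  }
  dt <- cfg$dt
  n <- ceiling(duration / dt)

  lti <- inherits(plant, "plant_params")
  if (lti) {
    d <- plant_discretize(plant, dt)
    x <- c(0, 0)
    T_now <- baseline
  } else {
    stopifnot(is.list(plant), inherits(plant$sar, "sar_model"))
    sys <- thermal_system(plant$geom, plant$props)
    A <- Matrix::Diagonal(x = sys$M / dt) + sys$K
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(A))
    Tvec <- rep(plant$props$T_inf, length(sys$M))
    bT <- sys$Gb * plant$props$T_inf
    T_now <- probe_temp(sys, Tvec)
    baseline <- T_now
  }

  st <- control_state(cfg)
  u0 <- st$u
  rc_state <- u0
  gated <- FALSE
  dp <- dose_params()

  tm <- numeric(n); Tlog <- numeric(n); ulog <- numeric(n); Hlog <- numeric(n)
  glog <- integer(n); doselog <- numeric(n)
  ev_t <- numeric(0); ev_probe <- character(0); ev_T <- numeric(0)
  ev_act <- character(0)
  dose <- 0

  for (k in seq_len(n)) {
    t <- (k - 1) * dt
    T_meas <- T_now + if (!is.null(noise)) stats::rnorm(1, 0, noise$sd) else 0

    gate <- safety_gate(c(probe = T_meas), cfg$thresholds, u = NA_real_,
                        gated = gated, hysteresis = cfg$hysteresis)
    if (gate$gated != gated) {
      ev_t <- c(ev_t, t); ev_probe <- c(ev_probe, if (length(gate$tripped)) gate$tripped[1] else "probe")
      ev_T <- c(ev_T, T_meas)
      ev_act <- c(ev_act, if (gate$gated) "gate_on" else "gate_off")
      gated <- gate$gated
    }

    st <- pid_step(st, T_meas, cfg, freeze_integral = gated)
    u_cmd <- if (gated) 0 else st$u

    u_act <- if (cfg$rc_enabled) {
      rc_state <- rc_state + (1 - exp(-dt / cfg$rc_tau)) * (u_cmd - rc_state)
      rc_state
    } else {
      rc_state <- u_cmd
      u_cmd
    }
    H <- actuator_map(u_act, cfg, drive)

    if (lti) {
      x <- d$Ad %*% x + d$Bd * u_act
      T_now <- baseline + x[2]
    } else {
      q <- (plant$sar$c_sar * H^2) * sys$wire_vol
      rhs <- sys$M / dt * Tvec + q + bT
      Tvec <- as.vector(Matrix::solve(ch, rhs))
      T_now <- probe_temp(sys, Tvec)
    }
    dose <- dose + dt / 60 *
      (if (T_now >= dp$breakpoint) dp$r_above else dp$r_below)^(dp$breakpoint - T_now)

    tm[k] <- t + dt; Tlog[k] <- T_now; ulog[k] <- u_cmd; Hlog[k] <- H
    glog[k] <- as.integer(gated); doselog[k] <- dose
  }

  trace <- temperature_trace(c(0, tm), c(baseline, Tlog),
                             u_V = c(u0, ulog),
                             H_kA_per_m = c(actuator_map(u0, cfg, drive), Hlog),
                             gated = c(0L, glog),
                             cem43_min = c(0, doselog))
  metrics <- if (cfg$setpoint > baseline) {
    transient_metrics(trace, cfg$setpoint)
  } else NULL
  structure(list(trace = trace,
                 events = data.frame(time_s = ev_t, probe = ev_probe,
                                     temperature_C = ev_T, action = ev_act),
                 dose = dose, metrics = metrics, config = cfg),
            class = "closed_loop_run")
}

#' @export
print.closed_loop_run <- function(x, ...) {
  cat(sprintf("<closed_loop_run> %d steps, dt = %g s, setpoint %g degC\n",
              nrow(x$trace) - 1L, x$config$dt, x$config$setpoint))
  cat(sprintf("  final T = %.3f degC, CEM43 = %.2f min, %d safety events\n",
              x$trace$T_probe_C[nrow(x$trace)], x$dose, nrow(x$events)))
  if (!is.null(x$metrics)) {
    cat(sprintf("  tr = %.1f s, Mp = %.3f, tss = %.1f s, ess = %.4f K\n",
                x$metrics$tr, x$metrics$mp, x$metrics$tss, x$metrics$ess))
  }
  invisible(x)
}
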