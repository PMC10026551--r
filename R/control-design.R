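#' Transient performance specification
#'
#' Performance requirements for the closed-loop temperature response of a
#' hyperthermia controller: rise time to the set point, settling time into a
#' fixed band, maximum fractional overshoot, and the clinically relevant
#' treatment window over which the set point must be held.
#'
#' @param tr_max maximum 10--90% rise time, seconds.
#' @param tss_max maximum settling time, seconds.
#' @param mp_max maximum fractional overshoot, in (0, 1).
#' @param settle_band half-width of the settling band, kelvin.
#' @param treatment_window length-2 vector (min, max) hold duration, seconds.
#' @return A `transient_spec` object.
#' @examples
#' transient_spec() # the defaults: tr < 60 s, tss < 300 s, Mp < 0.05
#' @export
transient_spec <- function(tr_max = 60, tss_max = 300, mp_max = 0.05,
                           settle_band = 0.5,
                           treatment_window = c(900, 1800)) {
  stopifnot(tr_max > 0, tss_max > 0, settle_band > 0,
            length(treatment_window) == 2, all(treatment_window > 0),
            treatment_window[1] <= treatment_window[2])
  if (mp_max <= 0 || mp_max >= 1) {
    stop("mp_max must be a fraction strictly inside (0, 1)")
  }
  structure(list(tr_max = tr_max, tss_max = tss_max, mp_max = mp_max,
                 settle_band = settle_band,
                 treatment_window = treatment_window),
            class = "transient_spec")
}

#' Fractional overshoot of a second-order step response
#'
#' For a standard underdamped second-order system the peak overshoot is
#' `Mp = exp(-pi * zeta / sqrt(1 - zeta^2))`. At critical damping (`zeta = 1`)
#' the overshoot is 0 (taken as the limit).
#'
#' @param zeta damping ratio in \[0, 1\].
#' @return Overshoot as a fraction of the step amplitude.
#' @examples
#' overshoot_from_zeta(0.69) # ~ 0.05
#' @export
overshoot_from_zeta <- function(zeta) {
  if (any(zeta < 0) || any(zeta > 1)) stop("zeta must lie in [0, 1]")
  ifelse(zeta >= 1, 0, exp(-pi * zeta / sqrt(1 - zeta^2)))
}

#' Map transient requirements to an s-plane pole region
#'
#' Applies the classical second-order design rules: `omega_n > 1.8 / tr`,
#' `sigma > 4.6 / tss`, and a damping-ratio floor obtained by numerically
#' inverting the overshoot formula at `mp_max`. Closed-loop poles inside the
#' returned region satisfy all three transient requirements simultaneously.
#'
#' @param spec a [transient_spec()].
#' @return A `pole_region` with fields `omega_n_min` (rad/s), `sigma_min`
#'   (1/s), `zeta_min`, `zeta_max` (= 1).
#' @examples
#' spec_to_pole_region(transient_spec(60, 300, 0.05))
#' @export
spec_to_pole_region <- function(spec) {
  stopifnot(inherits(spec, "transient_spec"))
  structure(list(omega_n_min = 1.8 / spec$tr_max,
                 sigma_min   = 4.6 / spec$tss_max,
                 zeta_min    = zeta_for_overshoot(spec$mp_max),
                 zeta_max    = 1),
            class = "pole_region")
}

# Invert Mp(zeta) = mp by bisection on [0, 1 - 1e-9], deterministic, to
# |Mp(zeta) - mp| < 1e-10. (The closed form ln(1/mp)/sqrt(pi^2 + ln(mp)^2)
# is used as an independent oracle in the tests.)
zeta_for_overshoot <- function(mp, tol = 1e-10) {
  if (mp <= 0 || mp >= 1) stop("overshoot must be a fraction in (0, 1)")
  lo <- 0; hi <- 1 - 1e-9
  repeat {
    mid <- (lo + hi) / 2
    f <- overshoot_from_zeta(mid) - mp # decreasing in zeta
    if (abs(f) < tol || (hi - lo) < 1e-15) return(mid)
    if (f > 0) lo <- mid else hi <- mid
  }
}

#' Target closed-loop pole pair
#'
#' Packages the damping ratio and natural frequency of the desired
#' second-order closed loop `Q(s) = omega_n^2 / (s^2 + 2 zeta omega_n s +
#' omega_n^2)` together with the derived pole real part `sigma = zeta *
#' omega_n` and damped frequency `omega_d = omega_n * sqrt(1 - zeta^2)`.
#'
#' @param zeta damping ratio in \[0, 1\].
#' @param omega_n undamped natural frequency, rad/s.
#' @return A `closed_loop_target`.
#' @examples
#' closed_loop_target(1, 0.2) # the critically damped design point
#' @export
closed_loop_target <- function(zeta, omega_n) {
  if (zeta < 0 || zeta > 1) stop("zeta must lie in [0, 1]")
  stopifnot(omega_n > 0)
  structure(list(zeta = zeta, omega_n = omega_n,
                 sigma = zeta * omega_n,
                 omega_d = omega_n * sqrt(1 - zeta^2)),
            class = "closed_loop_target")
}

#' Two-time-constant plant model
#'
#' The gel + wire heating plant is modeled as
#' `P(s) = g / ((tau1 s + 1) (tau2 s + 1))` with static gain `g` (K/V) and a
#' fast and a slow time constant. `tau63 = tau1 + tau2` is the time for the
#' step response to reach ~63% of its total gain.
#'
#' @param g static gain, K per V of control input.
#' @param tau1 fast time constant, seconds.
#' @param tau2 slow time constant, seconds; must exceed `tau1`.
#' @return A `plant_params` object.
#' @examples
#' plant_params(95.83, 2.96, 249.04) # the identified gel + Cu wire phantom
#' @export
plant_params <- function(g, tau1, tau2) {
  stopifnot(g > 0, tau1 > 0, tau2 > tau1)
  structure(list(g = g, tau1 = tau1, tau2 = tau2, tau63 = tau1 + tau2),
            class = "plant_params")
}

#' PID gains with filtered derivative
#'
#' Controller `C(s) = Kp + Ki/s + Kd s / (1 + tau_d s)`. Gains act on a
#' temperature error in kelvin; `kappa` is the integral-gain scale from the
#' pole-placement derivation (`ki = kappa`).
#'
#' @param kp proportional gain, 1/K.
#' @param ki integral gain, 1/(s K).
#' @param kd derivative gain, s/K (non-negative).
#' @param tau_d derivative filter time constant, seconds.
#' @param kappa pole-placement gain scale, 1/(s K); defaults to `ki`.
#' @return A `pid_gains` object.
#' @export
pid_gains <- function(kp, ki, kd = 0, tau_d = 1, kappa = ki) {
  stopifnot(kp > 0 || ki > 0 || kd >= 0, ki >= 0, kd >= 0, tau_d > 0)
  structure(list(kp = kp, ki = ki, kd = kd, tau_d = tau_d, kappa = kappa),
            class = "pid_gains")
}

#' Synthesize PID gains by pole placement
#'
#' Places the closed-loop poles of the two-lag plant at the target
#' second-order pair by choosing `C(s) = Q(s) / ((1 - Q(s)) P(s))`, which for
#' this plant reduces to a PID with filtered derivative:
#' `tau_d = 1/(2 zeta omega_n)`, `kappa = omega_n / (2 zeta g)`,
#' `Kp = kappa (tau1 + tau2 - tau_d)`, `Ki = kappa`,
#' `Kd = kappa (tau1 - tau_d)(tau2 - tau_d)`.
#' With these gains the closed loop equals `Q(s)` exactly (in continuous
#' time), so the transient specification carries over verbatim.
#'
#' A negative raw `Kd` (possible when `tau1 < tau_d < tau2`, i.e. the plant's
#' fast lag is quicker than the derivative filter) is floored at zero with a
#' warning: a negative derivative gain is destabilizing in the discrete loop.
#'
#' @param plant a [plant_params()].
#' @param target a [closed_loop_target()]; `zeta > 0` required.
#' @return A [pid_gains()] object.
#' @examples
#' design_pid(plant_params(95.83, 2.96, 249.04), closed_loop_target(1, 0.2))
#' @export
design_pid <- function(plant, target) {
  stopifnot(inherits(plant, "plant_params"),
            inherits(target, "closed_loop_target"))
  if (target$zeta <= 0) stop("zeta = 0 target: derivative filter constant undefined")
  tau_d <- 1 / (2 * target$zeta * target$omega_n)
  kappa <- target$omega_n / (2 * target$zeta * plant$g)
  kp <- kappa * (plant$tau1 + plant$tau2 - tau_d)
  kd <- kappa * (plant$tau1 - tau_d) * (plant$tau2 - tau_d)
  if (kd < 0) {
    warning(sprintf("raw derivative gain %.4g < 0 (tau1 < tau_d); floored at 0", kd))
    kd <- 0
  }
  pid_gains(kp = kp, ki = kappa, kd = kd, tau_d = tau_d, kappa = kappa)
}

#' Analytic step response of the target closed loop
#'
#' Samples the closed-form unit-DC-gain second-order step response of
#' `Q(s)` at interval `dt`. Serves as the oracle against which the discrete
#' closed loop is verified.
#'
#' @param target a [closed_loop_target()].
#' @param step step amplitude, kelvin.
#' @param duration trace length, seconds.
#' @param dt sampling interval, seconds; must satisfy `dt < 0.1 / omega_n`.
#' @param baseline temperature before the step, degrees Celsius.
#' @return A [temperature_trace()].
#' @export
simulate_reference_response <- function(target, step, duration, dt,
                                        baseline = 0) {
  stopifnot(inherits(target, "closed_loop_target"), dt > 0, duration > dt)
  if (dt >= 0.1 / target$omega_n) {
    stop("dt must resolve the target dynamics: dt < 0.1/omega_n")
  }
  t <- seq(0, duration, by = dt)
  z <- target$zeta; wn <- target$omega_n
  y <- if (z >= 1) {
    1 - (1 + wn * t) * exp(-wn * t)
  } else if (z == 0) {
    1 - cos(wn * t)
  } else {
    wd <- target$omega_d; s <- target$sigma
    1 - exp(-s * t) * (cos(wd * t) + s / wd * sin(wd * t))
  }
  temperature_trace(t, baseline + step * y)
}

#' Transient metrics of a step-response trace
#'
#' Computes rise time (10--90% of the set-point change, with linear
#' interpolation between samples), fractional overshoot (floored at 0),
#' settling time (first instant after which the trace stays inside the band
#' for the remainder of the record), and steady-state error (mean absolute
#' error over the final 10% of the trace).
#'
#' @param trace a [temperature_trace()].
#' @param setpoint target temperature, degrees Celsius; must exceed the
#'   initial temperature.
#' @param band settling band half-width, kelvin.
#' @return List with `tr`, `mp`, `tss`, `ess`. `tr` is `NA` (with a warning)
#'   if the trace never reaches 90% of the commanded change; `tss` is `NA`
#'   if the trace never settles.
#' @export
transient_metrics <- function(trace, setpoint, band = 0.5) {
  t <- trace$time_s; T <- trace$T_probe_C
  T0 <- T[1]
  if (setpoint <= T0) stop("setpoint must exceed the initial temperature")
  y <- (T - T0) / (setpoint - T0)

  cross <- function(level) {
    i <- which(y >= level)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(t[1])
    t[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  }
  t10 <- cross(0.1); t90 <- cross(0.9)
  tr <- if (is.na(t90)) {
    warning("trace never reaches 90% of the commanded change; rise time undefined")
    NA_real_
  } else t90 - t10

  mp <- max(0, (max(T) - setpoint) / (setpoint - T0))

  inside <- abs(T - setpoint) <= band
  tss <- if (!inside[length(inside)]) NA_real_ else {
    last_out <- max(c(0L, which(!inside)))
    if (last_out == 0L) 0 else t[last_out + 1L] - t[1]
  }

  tail_idx <- seq.int(max(1L, ceiling(0.9 * length(T))), length(T))
  ess <- mean(abs(T[tail_idx] - setpoint))

  list(tr = tr, mp = mp, tss = tss, ess = ess)
}

#' Small worked-arithmetic helpers for overshoot and decay rate
#'
#' `overshoot_peak()` returns the peak temperature corresponding to a
#' fractional overshoot above a set point (e.g. 5% at 45 degC gives
#' 47.25 degC). `decay_rate()` returns the exponential decay rate `sigma`
#' (1/s) that shrinks an oscillation envelope from `amp0` to `amp1` kelvin in
#' `t` seconds, `sigma = log(amp0/amp1) / t`.
#'
#' @param setpoint set point, degrees Celsius.
#' @param mp fractional overshoot.
#' @return Peak temperature in degrees Celsius.
#' @export
overshoot_peak <- function(setpoint, mp) setpoint * (1 + mp)

#' @rdname overshoot_peak
#' @param amp0,amp1 initial and final envelope amplitudes, kelvin.
#' @param t elapsed time, seconds.
#' @export
decay_rate <- function(amp0, amp1, t) {
  stopifnot(amp0 > 0, amp1 > 0, t > 0)
  log(amp0 / amp1) / t
}
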