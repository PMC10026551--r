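#' Static gain from a step experiment
#'
#' The plant's static gain is the saturation temperature rise divided by the
#' control-input step that produced it, `g = delta_T / u_step` (K/V).
#'
#' @param delta_T total temperature rise at saturation, kelvin.
#' @param u_step control input step, volts; must be nonzero.
#' @return Gain in K/V.
#' @examples
#' static_gain(23, 0.24) # 95.83 K/V, the gel + Cu wire phantom
#' @export
static_gain <- function(delta_T, u_step) {
  if (u_step == 0) stop("u_step must be nonzero")
  delta_T / u_step
}

#' Step-response trace for identification
#'
#' @param times sample times, seconds, uniform.
#' @param temperatures probe temperature, degrees Celsius.
#' @param u_step input step magnitude, volts (> 0).
#' @param step_time time at which the step was applied, seconds.
#' @return A `step_response_trace`.
#' @export
step_response_trace <- function(times, temperatures, u_step, step_time = 0) {
  stopifnot(length(times) == length(temperatures), u_step > 0)
  check_uniform_time(times)
  structure(list(times = times, temperatures = temperatures,
                 u_step = u_step, step_time = step_time),
            class = "step_response_trace")
}

# centered moving average; ends padded by shrinking the window
moving_average <- function(x, n) {
  if (n <= 1) return(x)
  half <- floor(n / 2)
  idx <- seq_along(x)
  vapply(idx, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Identify the two-lag plant from a step response
#'
#' Graphical ("inflection") method: the fast constant `tau1` is read as the
#' delay from the step to the instant of maximum heating rate, `tau63` as the
#' time to reach 63% of the total rise, and `tau2 = tau63 - tau1`. Because
#' the inflection delay only approximates `tau1` for widely separated lags,
#' the graphical estimate is scored by its residual and, when that residual
#' exceeds `tol_frac` of the total rise (or when `method = "fit"`), refined
#' by a two-exponential least-squares fit of the overdamped step response
#' (the refined result is what satisfies parameter-recovery round trips).
#'
#' @param trace a [step_response_trace()]. The heating segment should reach
#'   at least ~99% of its asymptote, or `asymptote` must be supplied.
#' @param asymptote optional known saturation temperature, degrees Celsius.
#' @param method `"auto"` (default: inflection, escalate to fit on poor
#'   residual), `"inflection"`, or `"fit"`.
#' @param smooth_n moving-average pre-smoother width, samples.
#' @param tol_frac residual tolerance (fraction of total rise) above which
#'   `"auto"` escalates to the least-squares fit.
#' @return An `identification_result`: list with `plant` ([plant_params()]),
#'   `method` label, and `residual_rms` (kelvin).
#' @export
identify_time_constants <- function(trace, asymptote = NULL,
                                    method = c("auto", "inflection", "fit"),
                                    smooth_n = 5, tol_frac = 0.002) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "step_response_trace"))
  keep <- trace$times >= trace$step_time
  t <- trace$times[keep] - trace$step_time
  T <- trace$temperatures[keep]
  dt <- t[2] - t[1]
  T0 <- if (any(trace$times < trace$step_time)) {
    mean(trace$temperatures[trace$times < trace$step_time])
  } else T[1]

  Ts <- moving_average(T, smooth_n)
  resid_sd <- stats::mad(diff(T - Ts), constant = 1.4826)
  # heating segment must rise monotonically beyond noise
  drops <- diff(Ts) < -3 * max(resid_sd, .Machine$double.eps)
  rise_span <- Ts <= T0 + 0.95 * (max(Ts) - T0)
  if (any(drops & rise_span[-1])) {
    stop("non-monotone heating segment beyond noise tolerance; not a step response")
  }

  T_inf <- if (!is.null(asymptote)) asymptote else {
    tail_n <- max(5L, ceiling(0.02 * length(T)))
    mean(T[seq.int(length(T) - tail_n + 1L, length(T))])
  }
  dT_tot <- T_inf - T0
  if (dT_tot <= 0) stop("no temperature rise in trace")

  # inflection (graphical) estimates
  slope <- c(NA, diff(Ts)) / dt
  tau1_g <- t[which.max(slope)]
  i63 <- which(Ts >= T0 + 0.63 * dT_tot)[1]
  if (is.na(i63)) stop("trace never reaches 63% of its total rise")
  tau63_g <- if (i63 == 1) t[1] else {
    lev <- T0 + 0.63 * dT_tot
    t[i63 - 1] + (lev - Ts[i63 - 1]) / (Ts[i63] - Ts[i63 - 1]) * dt
  }
  tau2_g <- tau63_g - tau1_g
  tau1_g <- max(tau1_g, dt / 2) # first-order limit: estimate below resolution
  if (tau2_g <= tau1_g) tau2_g <- tau1_g * 1.001

  model_resid <- function(g, tau1, tau2) {
    pred <- T0 + plant_step_response(plant_params(g, tau1, tau2), trace$u_step, t)
    sqrt(mean((T - pred)^2))
  }
  g_hat <- static_gain(dT_tot, trace$u_step)
  res_g <- model_resid(g_hat, tau1_g, tau2_g)

  out <- list(plant = plant_params(g_hat, tau1_g, tau2_g),
              method = "inflection", residual_rms = res_g)

  if (method == "fit" || (method == "auto" && res_g > tol_frac * dT_tot)) {
    # robust tau63 from a heavily smoothed curve anchors the start values;
    # bounds keep the optimizer in the physically sensible decade
    w63 <- max(smooth_n, min(round(length(t) / 150), 101))
    Th <- moving_average(T, w63)
    i63h <- which(Th >= T0 + 0.63 * dT_tot)[1]
    tau63_s <- if (is.na(i63h)) tau63_g else max(t[i63h], 2 * dt)
    # the baseline is a free (tightly bounded) offset: its prior uncertainty
    # shrinks with the number of pre-step samples averaged into T0
    n_pre <- sum(trace$times < trace$step_time)
    bw <- max(3 * resid_sd / sqrt(max(n_pre, 1)), 1e-6 * dT_tot)
    fit <- tryCatch({
      dat <- data.frame(t = t, dT = T - T0)
      minpack.lm::nlsLM(
        dT ~ c0 + dTi * (1 - (b * exp(-t / b) - a * exp(-t / a)) / (b - a)),
        data = dat,
        start = list(c0 = 0, dTi = dT_tot, a = tau63_s / 20, b = tau63_s),
        lower = c(c0 = -bw, dTi = dT_tot * 0.5, a = dt / 20, b = tau63_s / 4),
        upper = c(c0 = bw, dTi = dT_tot * 2, a = tau63_s, b = 4 * tau63_s),
        control = minpack.lm::nls.lm.control(maxiter = 300))
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      tau1_f <- min(cf[["a"]], cf[["b"]]); tau2_f <- max(cf[["a"]], cf[["b"]])
      if (tau2_f <= tau1_f) tau2_f <- tau1_f * 1.001
      g_f <- static_gain(cf[["dTi"]], trace$u_step)
      res_f <- model_resid(g_f, tau1_f, tau2_f)
      if (res_f < res_g || method == "fit") {
        out <- list(plant = plant_params(g_f, tau1_f, tau2_f),
                    method = "two-exponential fit", residual_rms = res_f)
      }
    }
  }
  class(out) <- "identification_result"
  out
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("<identification_result> method: %s, residual RMS %.4g K\n",
              x$method, x$residual_rms))
  cat(sprintf("  g = %.4g K/V, tau1 = %.4g s, tau2 = %.4g s, tau63 = %.4g s\n",
              x$plant$g, x$plant$tau1, x$plant$tau2, x$plant$tau63))
  invisible(x)
}

#' Natural frequency from an oscillation period
#'
#' `omega_n = 2 pi / period`, used to read the undamped natural frequency
#' off a proportional-only closed-loop oscillation.
#'
#' @param period oscillation period, seconds.
#' @return Angular frequency in rad/s.
#' @examples
#' natural_frequency_from_period(31.1) # ~0.2 rad/s
#' @export
natural_frequency_from_period <- function(period) {
  stopifnot(period > 0)
  2 * pi / period
}

#' Oscillation period from a temperature trace
#'
#' Smooths the trace with a short moving average, locates local maxima above
#' the noise floor (first sample of any plateau), and returns the mean
#' spacing of successive peaks.
#'
#' @param trace a [temperature_trace()].
#' @param smooth_n moving-average width, samples.
#' @return Mean peak spacing, seconds.
#' @export
estimate_period_from_oscillation <- function(trace, smooth_n = 5) {
  t <- trace$time_s
  y <- moving_average(trace$T_probe_C, smooth_n)
  n <- length(y)
  # strict rise into the peak, non-increase after; plateau -> first sample
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- which(is_peak)
  if (length(peaks) > 1) { # drop immediately adjacent duplicates on plateaus
    peaks <- peaks[c(TRUE, diff(peaks) > 1)]
  }
  # noise floor: keep peaks with height above the trace midline
  floor_level <- stats::median(y) + 0.1 * (max(y) - stats::median(y))
  peaks <- peaks[y[peaks] > floor_level]
  if (length(peaks) < 3) {
    stop("fewer than 3 local maxima above the noise floor; cannot estimate period")
  }
  mean(diff(t[peaks]))
}
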