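#' Zero-order-hold discretization of the two-lag plant
#'
#' Converts `P(s) = g / ((tau1 s + 1)(tau2 s + 1))` into an exact
#' discrete-time state-space update for piecewise-constant input held over
#' each interval `dt` (zero-order hold), via the augmented matrix
#' exponential. The state is `(x1, x2)` with `x2` the plant output in kelvin
#' above baseline.
#'
#' @param plant a [plant_params()].
#' @param dt control interval, seconds.
#' @return List with matrices `Ad` (2x2) and `Bd` (2x1); advance one step
#'   with `x <- Ad %*% x + Bd * u`.
#' @export
plant_discretize <- function(plant, dt) {
  stopifnot(inherits(plant, "plant_params"), dt > 0)
  A <- rbind(c(-1 / plant$tau1, 0),
             c(plant$g / plant$tau2, -1 / plant$tau2))
  B <- c(1 / plant$tau1, 0)
  aug <- rbind(cbind(A, B), 0) * dt
  E <- as.matrix(Matrix::expm(Matrix::Matrix(aug)))
  list(Ad = E[1:2, 1:2], Bd = E[1:2, 3])
}

#' Open-loop response of the two-lag plant to an arbitrary input
#'
#' Simulates `P(s)` under a zero-order-hold input sequence. For a constant
#' step input this matches the closed form
#' `g u (1 - (tau2 e^(-t/tau2) - tau1 e^(-t/tau1)) / (tau2 - tau1))`.
#'
#' @param plant a [plant_params()].
#' @param u input vector (volts), one value per control interval.
#' @param dt sampling interval, seconds.
#' @param baseline output offset added to the response, degrees Celsius.
#' @return A [temperature_trace()] with `length(u) + 1` samples starting at
#'   the baseline.
#' @examples
#' p <- plant_params(95.83, 2.96, 249.04)
#' tr <- lti_response(p, rep(0.24, 300), dt = 1)
#' @export
lti_response <- function(plant, u, dt, baseline = 0) {
  d <- plant_discretize(plant, dt)
  n <- length(u)
  y <- numeric(n + 1)
  x <- c(0, 0)
  for (k in seq_len(n)) {
    x <- d$Ad %*% x + d$Bd * u[k]
    y[k + 1] <- x[2]
  }
  temperature_trace(seq(0, n * dt, by = dt), baseline + y)
}

#' Analytic step response of the two-lag plant
#'
#' Closed-form overdamped step response, used as the noiseless fixture for
#' identification tests and as an oracle for the discretized simulator.
#'
#' @param plant a [plant_params()].
#' @param u_step step input, volts.
#' @param t time vector, seconds (step applied at t = 0).
#' @return Temperature rise above baseline, kelvin.
#' @export
plant_step_response <- function(plant, u_step, t) {
  t1 <- plant$tau1; t2 <- plant$tau2
  plant$g * u_step *
    (1 - (t2 * exp(-t / t2) - t1 * exp(-t / t1)) / (t2 - t1))
}
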