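test_that("pid_step implements the proportional law and stays bounded", {
  cfg <- controller_config(pid_gains(0.26, 1e-12, 0, tau_d = 1),
                           setpoint = 27, mode = "normalized",
                           u_min = -10, u_max = 10)
  st <- pid_step(control_state(cfg), T_meas = 25, cfg)
  expect_equal(st$u, 0.52, tolerance = 1e-9)
  # zero error from rest: output rests at the floor
  cfg2 <- controller_config(pid_gains(0.26, 1e-3, 0.1, tau_d = 2.5),
                            setpoint = 25, mode = "volts")
  st2 <- control_state(cfg2)
  for (i in 1:20) st2 <- pid_step(st2, 25, cfg2)
  expect_equal(st2$u, cfg2$u_min)
  # large error: clamped at the ceiling
  st3 <- pid_step(control_state(cfg2), T_meas = 0, cfg2)
  expect_equal(st3$u, cfg2$u_max)
})

test_that("actuator map hits the measured anchors in both modes", {
  cfgn <- controller_config(phantom_gains(), 45, mode = "normalized")
  drv <- field_drive(0, H_max = 9.8)
  expect_equal(actuator_map(1, cfgn, drv), 9.8)
  expect_equal(actuator_map(0, cfgn, drv), 0)
  expect_equal(actuator_map(1.7, cfgn, drv), 9.8) # clamped
  cfgv <- controller_config(phantom_gains(), 45, mode = "volts")
  expect_equal(actuator_map(0.25, cfgv, drv), 4.2)
  expect_equal(actuator_map(1.25, cfgv, drv), 9.8)
  expect_equal(actuator_map(0, cfgv, drv), 0)
  expect_equal(actuator_map(0.75, cfgv, drv), (4.2 + 9.8) / 2)
})

test_that("RC limiter bounds the slew rate at the fault threshold", {
  dt <- 0.001
  u <- c(0.25, rep(1.25, 3000))
  y <- rc_limit(u, rc_tau = 0.2, dt = dt)
  slopes <- diff(y) / dt
  expect_lte(max(abs(slopes)), 5)
  expect_equal(max(slopes), (1 - exp(-dt / 0.2)) / dt, tolerance = 1e-9)
  expect_equal(max(slopes), 5, tolerance = 0.01)
  # constant input: converges, slope dies away
  expect_equal(y[length(y)], 1.25, tolerance = 1e-6)
  expect_lt(abs(slopes[length(slopes)]), 1e-4)
  # slow ramp passes with slope no larger than the input slope
  ramp <- seq(0.25, 1.25, length.out = 2001) # 0.5 V/s at dt = 1 ms
  yr <- rc_limit(ramp, 0.2, dt)
  expect_lte(max(diff(yr) / dt), max(diff(ramp) / dt) + 1e-9)
  expect_warning(rc_limit(c(0, 1), rc_tau = 0.2, dt = 0.15), "poorly resolved")
})

test_that("safety gate is a strict relay with fail-safe on missing readings", {
  th <- c(probe = 25)
  expect_equal(safety_gate(c(probe = 25.1), th, u = 0.8)$u, 0)
  g <- safety_gate(c(probe = 24.9), th, u = 0.8)
  expect_equal(g$u, 0.8)
  expect_false(g$gated)
  # NA reading closes the gate
  gna <- safety_gate(c(probe = NA_real_), th, u = 0.8)
  expect_true(gna$gated)
  expect_equal(gna$u, 0)
  # a probe named in thresholds but absent from the readings is a fault
  g2 <- safety_gate(c(probe = 20), c(probe = 25, safety = 39), u = 0.8)
  expect_true(g2$gated)
  # hysteresis holds the gate until the release band clears
  gh <- safety_gate(c(probe = 24.8), th, u = 0.8, gated = TRUE, hysteresis = 0.5)
  expect_true(gh$gated)
  gh2 <- safety_gate(c(probe = 24.4), th, u = 0.8, gated = TRUE, hysteresis = 0.5)
  expect_false(gh2$gated)
})

test_that("CEM43 reproduces hand-computed doses and is additive", {
  expect_equal(cem43(rep(43, 600), dt = 1), 10)
  expect_equal(cem43(rep(45, 900), dt = 1), 60)
  expect_equal(cem43(rep(41, 600), dt = 1), 0.625)
  # brute-force oracle on a mixed trace
  set.seed(3)
  temps <- runif(500, 40, 46)
  brute <- sum(ifelse(temps >= 43, 0.5, 0.25)^(43 - temps)) * 2 / 60
  expect_equal(cem43(temps, dt = 2), brute, tolerance = 1e-12)
  # additivity over concatenated trace segments
  t <- seq(0, 600, by = 0.5)
  Tfull <- 37 + 8 * pmin(t / 120, 1)
  full <- temperature_trace(t, Tfull)
  a <- temperature_trace(t[t <= 300], Tfull[t <= 300])
  b <- temperature_trace(t[t >= 300], Tfull[t >= 300])
  expect_equal(cem43(full), cem43(a) + cem43(b), tolerance = 1e-12)
})

test_that("integral action removes steady-state error for in-range steps", {
  p <- phantom_plant()
  g <- phantom_gains()
  for (sp in c(24, 26, 29)) {
    cfg <- controller_config(g, setpoint = sp, mode = "normalized",
                             thresholds = c(probe = 60))
    run <- run_closed_loop(p, cfg, duration = 1500, baseline = 21.1)
    expect_lt(abs(run$trace$T_probe_C[nrow(run$trace)] - sp), 0.01)
  }
})

test_that("negligible gains leave the plant at baseline", {
  cfg <- controller_config(pid_gains(1e-12, 0, 0, tau_d = 1),
                           setpoint = 30, mode = "normalized",
                           thresholds = c(probe = 60))
  run <- with_quiet_metrics(
    run_closed_loop(phantom_plant(), cfg, duration = 60, baseline = 21.1))
  expect_lt(max(abs(run$trace$T_probe_C - 21.1)), 1e-6)
})

test_that("anti-windup recovery shows no secondary overshoot", {
  # a long saturated transient (large step, tight actuator ceiling)
  p <- phantom_plant()
  g <- phantom_gains()
  cfg <- controller_config(g, setpoint = 40, mode = "normalized",
                           thresholds = c(probe = 60))
  run <- run_closed_loop(p, cfg, duration = 1200, baseline = 21.1)
  # linear design overshoot is 0 (critically damped); allow 1% of the step
  expect_lt(run$metrics$mp, 0.01)
  expect_lt(abs(run$trace$T_probe_C[nrow(run$trace)] - 40), 0.02)
})

test_that("a threshold below the set point produces bounded relay cycling", {
  p <- phantom_plant()
  cfg <- controller_config(phantom_gains(), setpoint = 30,
                           mode = "normalized", thresholds = c(probe = 25))
  run <- with_quiet_metrics(
    run_closed_loop(p, cfg, duration = 600, baseline = 21.1))
  expect_gt(nrow(run$events), 4)
  expect_true(all(rle(run$events$action)$lengths == 1)) # strict alternation
  expect_lt(max(run$trace$T_probe_C), 27) # bounded excursion
  # safety dominance: command is zero on the step after any exceedance
  over <- which(head(run$trace$T_probe_C, -1) > 25)
  expect_true(all(run$trace$u_V[over + 1] == 0))
})

test_that("closed loop over the thermal plant reaches its set point", {
  geom <- phantom_geometry(grid_nr = 18, grid_nz = 36)
  props <- material_props()
  sar <- calibrate_sar(geom, props, 23, 9.78)
  # identify this phantom and tune for it so the loop is self-consistent
  tr <- simulate_thermal(geom, props, field_drive(9.78), sar, dt = 1,
                         duration = 1600)
  fix <- step_response_trace(tr$time_s, tr$T_probe_C, u_step = 1)
  pl <- identify_time_constants(fix, asymptote = props$T_inf + 23)$plant
  g <- suppressWarnings(design_pid(pl, closed_loop_target(1, 0.2)))
  cfg <- controller_config(g, setpoint = 25, mode = "normalized",
                           thresholds = c(probe = 40), dt = 0.5)
  run <- run_closed_loop(list(geom = geom, props = props, sar = sar), cfg,
                         duration = 600, drive = field_drive(0, H_max = 9.78))
  expect_lt(abs(run$trace$T_probe_C[nrow(run$trace)] - 25), 0.25)
  expect_lt(run$metrics$mp, 0.05)
})

test_that("noisy runs require a seed and are reproducible", {
  cfg <- controller_config(phantom_gains(), setpoint = 26,
                           mode = "normalized", thresholds = c(probe = 60))
  expect_error(run_closed_loop(phantom_plant(), cfg, 30, baseline = 21.1,
                               noise = list(sd = 0.05)), "seed")
  r1 <- run_closed_loop(phantom_plant(), cfg, 120, baseline = 21.1,
                        noise = list(sd = 0.05), seed = 9)
  r2 <- run_closed_loop(phantom_plant(), cfg, 120, baseline = 21.1,
                        noise = list(sd = 0.05), seed = 9)
  expect_identical(r1$trace, r2$trace)
})
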