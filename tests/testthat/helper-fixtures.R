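# Shared fixtures: the identified gel + Cu wire plant and its tuned loop,
# plus generators for synthetic step-response traces.

phantom_plant <- function() plant_params(95.83, 2.96, 249.04)

phantom_target <- function() closed_loop_target(1, 0.2)

phantom_gains <- function() {
  design_pid(phantom_plant(), phantom_target())
}

# Step-response fixture with a pre-step baseline segment; noise_sd = 0 gives
# the analytic noiseless response.
make_step_fixture <- function(plant, u_step, dt = 0.2, t_end = 1500,
                              pre_s = 30, baseline = 20, noise_sd = 0) {
  t <- seq(-pre_s, t_end, by = dt)
  y <- baseline + ifelse(t < 0, 0, plant_step_response(plant, u_step, pmax(t, 0)))
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  step_response_trace(t, y, u_step, step_time = 0)
}

# Gaussian-noise SD giving a prescribed SNR (dB) against the post-step RMS
# of the clean response.
sd_for_snr <- function(plant, u_step, snr_db, dt = 0.2, t_end = 1500) {
  t <- seq(0, t_end, by = dt)
  sqrt(mean(plant_step_response(plant, u_step, t)^2)) / 10^(snr_db / 20)
}

# Small fast phantom configuration for thermal tests.
test_geom <- function(...) phantom_geometry(...)

with_quiet_metrics <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("rise time undefined", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}
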