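#' Verify a closed-loop run against the design requirements
#'
#' Evaluates a run (or bare trace) against the transient specification and
#' dose target, producing a pass/fail table with one row per requirement:
#' hold duration at the set point within the treatment window (1a), CEM43
#' within the dose target band (1b), rise time (1c), overshoot (1d),
#' settling time (1e), and safety dominance -- the commanded output is zero
#' at every logged step on which a monitored probe exceeded its threshold
#' (2a) -- plus gate-event bookkeeping consistency (2b). Requirements that
#' the record cannot support (e.g. a trace too short to settle, or no safety
#' channel logged) are reported as `"indeterminate"` rather than failed.
#'
#' @param run a `closed_loop_run` from [run_closed_loop()], or a
#'   [temperature_trace()] (then `setpoint` is required and safety rows are
#'   indeterminate unless the trace carries `u_V`/`gated` columns).
#' @param spec a [transient_spec()].
#' @param dose_target target CEM43, minutes; `NA` to skip the dose row.
#' @param dose_tol dose tolerance, minutes.
#' @param setpoint set point override, degrees Celsius.
#' @return A `verification_report`: data frame with columns `id`,
#'   `requirement`, `measured`, `limit`, `status`; attribute `pass` is
#'   `TRUE` only if every determinate row passes.
#' @export
verify_run <- function(run, spec = transient_spec(), dose_target = 60,
                       dose_tol = 5, setpoint = NULL) {
  if (inherits(run, "closed_loop_run")) {
    trace <- run$trace
    if (is.null(setpoint)) setpoint <- run$config$setpoint
    thresholds <- run$config$thresholds
  } else {
    trace <- run
    thresholds <- NULL
    if (is.null(setpoint)) stop("setpoint required when verifying a bare trace")
  }
  mt <- tryCatch(transient_metrics(trace, setpoint, band = spec$settle_band),
                 warning = function(w) suppressWarnings(
                   transient_metrics(trace, setpoint, band = spec$settle_band)))

  rows <- list()
  add <- function(id, req, measured, limit, ok) {
    status <- if (is.na(ok)) "indeterminate" else if (ok) "pass" else "fail"
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, requirement = req, measured = measured, limit = limit,
      status = status)
  }

  # 1a: hold duration within the settling band
  inband <- abs(trace$T_probe_C - setpoint) <= spec$settle_band
  hold_s <- sum(inband) * trace_dt(trace)
  add("1a", "hold duration at set point (s)", hold_s,
      sprintf(">= %g", spec$treatment_window[1]),
      if (trace$time_s[nrow(trace)] < spec$treatment_window[1]) NA
      else hold_s >= spec$treatment_window[1])

  # 1b: thermal dose
  dose <- if ("cem43_min" %in% names(trace)) trace$cem43_min[nrow(trace)]
          else cem43(trace)
  add("1b", "CEM43 dose (min)", dose,
      sprintf("%g +/- %g", dose_target, dose_tol),
      if (is.na(dose_target)) NA else abs(dose - dose_target) <= dose_tol)

  # 1c-1e: transients. A missing rise/settling time on a trace long enough
  # to judge is a failure; on a short trace it is indeterminate.
  span <- trace$time_s[nrow(trace)] - trace$time_s[1]
  add("1c", "rise time (s)", mt$tr, sprintf("< %g", spec$tr_max),
      if (!is.na(mt$tr)) mt$tr < spec$tr_max
      else if (span >= spec$tr_max) FALSE else NA)
  add("1d", "overshoot (fraction)", mt$mp, sprintf("< %g", spec$mp_max),
      mt$mp < spec$mp_max)
  add("1e", sprintf("settling time into +/-%g K (s)", spec$settle_band),
      mt$tss, sprintf("< %g", spec$tss_max),
      if (!is.na(mt$tss)) mt$tss < spec$tss_max
      else if (span >= spec$tss_max) FALSE else NA)

  # 2a: safety dominance over the log
  if (!is.null(thresholds) && length(thresholds) &&
      all(c("u_V", "gated") %in% names(trace))) {
    over <- trace$T_probe_C > thresholds[["probe"]]
    # one-step reaction latency: compare command on the step after the reading
    viol <- which(utils::head(over, -1) & utils::tail(trace$u_V, -1) > 0)
    add("2a", "safety dominance (violations)", length(viol), "= 0",
        length(viol) == 0)
    ok_alt <- !is.null(run$events) &&
      (nrow(run$events) == 0 ||
         all(rle(run$events$action)$lengths == 1))
    add("2b", "gate events alternate", nrow(run$events), "on/off alternating",
        ok_alt)
  } else {
    add("2a", "safety dominance (violations)", NA_real_, "= 0", NA)
    add("2b", "gate events alternate", NA_real_, "on/off alternating", NA)
  }

  rep <- do.call(rbind, rows)
  determinate <- rep$status != "indeterminate"
  attr(rep, "pass") <- all(rep$status[determinate] == "pass")
  class(rep) <- c("verification_report", "data.frame")
  rep
}

#' @export
print.verification_report <- function(x, ...) {
  cat("<verification_report>", if (attr(x, "pass")) "PASS" else "FAIL", "\n")
  df <- as.data.frame(x)
  df$measured <- signif(df$measured, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

# --- config serialization ----------------------------------------------------

#' Serialize design objects to/from flat config lists
#'
#' Round-trip converters between the toolkit's design objects and the flat
#' key-value config dialect of [read_config()]/[write_config()]. Keys use
#' section prefixes: `plant.g`, `spec.tr_max`, `target.zeta`, `gains.kp`.
#'
#' @param plant,spec,target,gains toolkit objects.
#' @param cfg a named list from [read_config()].
#' @return `*_to_config` return named lists; `*_from_config` rebuild the
#'   objects.
#' @name config-serialization
NULL

#' @rdname config-serialization
#' @export
plant_to_config <- function(plant) {
  list(`plant.g` = plant$g, `plant.tau1` = plant$tau1, `plant.tau2` = plant$tau2)
}

#' @rdname config-serialization
#' @export
plant_from_config <- function(cfg) {
  plant_params(cfg$`plant.g`, cfg$`plant.tau1`, cfg$`plant.tau2`)
}

#' @rdname config-serialization
#' @export
spec_to_config <- function(spec) {
  list(`spec.tr_max` = spec$tr_max, `spec.tss_max` = spec$tss_max,
       `spec.mp_max` = spec$mp_max, `spec.settle_band` = spec$settle_band,
       `spec.treatment_min` = spec$treatment_window[1],
       `spec.treatment_max` = spec$treatment_window[2])
}

#' @rdname config-serialization
#' @export
spec_from_config <- function(cfg) {
  transient_spec(cfg$`spec.tr_max`, cfg$`spec.tss_max`, cfg$`spec.mp_max`,
                 cfg$`spec.settle_band`,
                 c(cfg$`spec.treatment_min`, cfg$`spec.treatment_max`))
}

#' @rdname config-serialization
#' @export
target_to_config <- function(target) {
  list(`target.zeta` = target$zeta, `target.omega_n` = target$omega_n)
}

#' @rdname config-serialization
#' @export
target_from_config <- function(cfg) {
  closed_loop_target(cfg$`target.zeta`, cfg$`target.omega_n`)
}

#' @rdname config-serialization
#' @export
gains_to_config <- function(gains) {
  list(`gains.kp` = gains$kp, `gains.ki` = gains$ki, `gains.kd` = gains$kd,
       `gains.tau_d` = gains$tau_d)
}

#' @rdname config-serialization
#' @export
gains_from_config <- function(cfg) {
  pid_gains(cfg$`gains.kp`, cfg$`gains.ki`, cfg$`gains.kd`, cfg$`gains.tau_d`)
}
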