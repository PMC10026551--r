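#' Uniformly sampled temperature trace
#'
#' The central record type of the toolkit: a data frame with a strictly
#' increasing, uniformly spaced `time_s` column and a `T_probe_C` column in
#' degrees Celsius. Closed-loop runs add the control voltage `u_V`, the field
#' amplitude `H_kA_per_m`, the safety-gate flag `gated` (0/1), the running
#' thermal dose `cem43_min`, and optionally a second sensor `T_safety_C`.
#'
#' @param time_s numeric vector of sample times in seconds, uniform spacing.
#' @param T_probe_C probe temperature in degrees Celsius.
#' @param ... further columns (recycled to length of `time_s`), e.g. `u_V`,
#'   `H_kA_per_m`, `gated`, `cem43_min`, `T_safety_C`.
#' @return A `temperature_trace`, a data frame subclass.
#' @examples
#' tr <- temperature_trace(seq(0, 10, by = 0.1), 21.1 + seq(0, 10, by = 0.1))
#' trace_dt(tr)
#' @export
temperature_trace <- function(time_s, T_probe_C, ...) {
  stopifnot(is.numeric(time_s), is.numeric(T_probe_C),
            length(time_s) == length(T_probe_C))
  check_uniform_time(time_s)
  df <- data.frame(time_s = time_s, T_probe_C = T_probe_C, ...)
  class(df) <- c("temperature_trace", "data.frame")
  df
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf("<temperature_trace> %d samples, dt = %g s, span %g s\n",
              nrow(x), trace_dt(x), x$time_s[nrow(x)] - x$time_s[1]))
  cat("columns:", paste(names(x), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 4), ...)
  invisible(x)
}

#' Sampling interval of a trace
#' @param trace a [temperature_trace()].
#' @return The (uniform) sampling interval in seconds.
#' @export
trace_dt <- function(trace) {
  if (nrow(trace) < 2) stop("trace has fewer than 2 samples")
  trace$time_s[2] - trace$time_s[1]
}

# Uniformity check shared by the constructor and the CSV reader. Errors name
# the first offending row so malformed files are diagnosable.
check_uniform_time <- function(time_s, tol = 1e-9) {
  if (length(time_s) < 2) return(invisible(TRUE))
  d <- diff(time_s)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1]
    stop(sprintf("time_s not strictly increasing at row %d (%g -> %g)",
                 i + 1L, time_s[i], time_s[i + 1L]))
  }
  dt <- d[1]
  bad <- which(abs(d - dt) > tol * max(1, abs(dt)))
  if (length(bad)) {
    stop(sprintf("time_s not uniform at row %d (step %g, expected %g)",
                 bad[1] + 1L, d[bad[1]], dt))
  }
  invisible(TRUE)
}

#' Read a temperature trace from CSV
#'
#' The trace dialect is plain UTF-8 CSV with a header, comma separator and
#' decimal point. `time_s` and `T_probe_C` are mandatory; any further numeric
#' columns are kept as-is.
#'
#' @param path file path.
#' @return A [temperature_trace()].
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  for (col in c("time_s", "T_probe_C")) {
    if (!col %in% names(df)) {
      stop(sprintf("trace file '%s' is missing required column '%s'", path, col))
    }
  }
  check_uniform_time(df$time_s)
  class(df) <- c("temperature_trace", "data.frame")
  df
}

#' Write a temperature trace to CSV
#'
#' Numeric columns are written with 15 significant digits so that a
#' write/read round trip is an identity to better than 1e-9.
#'
#' @param trace a [temperature_trace()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  out <- lapply(df, function(x) {
    if (is.numeric(x)) formatC(x, digits = 15, format = "g") else x
  })
  utils::write.table(as.data.frame(out, check.names = FALSE), path,
                     sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a flat key-value config file
#'
#' Config files are plain text, one `key = value` pair per line; `#` starts a
#' comment. Keys use dotted section prefixes (`plant.g`, `spec.tr_max`, ...)
#' and carry explicit units in their names where ambiguity is possible.
#' Values that parse as numbers are returned numeric.
#'
#' @param path file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) != 3) stop(sprintf("malformed config line: '%s'", ln))
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' @rdname read_config
#' @param cfg named list of scalar values.
#' @export
write_config <- function(cfg, path) {
  vals <- vapply(cfg, function(v) {
    if (is.numeric(v)) formatC(v, digits = 15, format = "g") else as.character(v)
  }, character(1))
  writeLines(paste(names(cfg), "=", vals), path)
  invisible(path)
}
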