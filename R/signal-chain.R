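#' Raw high-rate sensor signal
#'
#' @param values signal samples (temperature-equivalent units).
#' @param sample_rate sampling rate, Hz (default 10 kHz, the acquisition
#'   rate of the fiber-optic readout path).
#' @return A `raw_signal` object.
#' @export
raw_signal <- function(values, sample_rate = 10000) {
  stopifnot(is.numeric(values), sample_rate > 0)
  structure(list(values = values, sample_rate = sample_rate),
            class = "raw_signal")
}

#' Low-pass filter specification
#'
#' Four-pole Butterworth with 100 Hz cutoff by default, well below the
#' Nyquist rate of the 10 kHz acquisition and far above the sub-hertz plant
#' dynamics.
#'
#' @param order filter order.
#' @param cutoff cutoff frequency, Hz.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(order = 4, cutoff = 100) {
  stopifnot(order >= 1, cutoff > 0)
  structure(list(order = as.integer(order), cutoff = cutoff),
            class = "filter_spec")
}

#' Sensor noise model
#'
#' Additive disturbances on the raw signal: white Gaussian noise, fixed RF
#' interference tones, and a DC offset. A seed is mandatory so fixtures are
#' reproducible.
#'
#' @param gaussian_sd white-noise standard deviation, signal units.
#' @param tone_freqs interference tone frequencies, Hz.
#' @param tone_amps tone amplitudes, signal units (recycled to the number
#'   of tones).
#' @param dc_offset constant offset, signal units.
#' @param seed integer RNG seed (required).
#' @return A `noise_model` object.
#' @export
noise_model <- function(gaussian_sd = 0, tone_freqs = numeric(0),
                        tone_amps = numeric(0), dc_offset = 0, seed) {
  if (missing(seed)) stop("noise_model requires an explicit seed")
  stopifnot(gaussian_sd >= 0, all(tone_amps >= 0))
  if (length(tone_freqs)) tone_amps <- rep_len(tone_amps, length(tone_freqs))
  structure(list(gaussian_sd = gaussian_sd, tone_freqs = tone_freqs,
                 tone_amps = tone_amps, dc_offset = dc_offset,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Synthesize a noisy high-rate sensor signal from a clean trace
#'
#' Upsamples the clean temperature trace to the acquisition rate by linear
#' interpolation and adds the noise model's Gaussian noise, interference
#' tones (random phases drawn from the seed), and DC offset. Deterministic
#' given the seed.
#'
#' @param clean a [temperature_trace()].
#' @param noise a [noise_model()].
#' @param sample_rate acquisition rate, Hz.
#' @return A [raw_signal()]; the time base starts at the clean trace's
#'   first sample.
#' @export
make_noisy_sensor <- function(clean, noise, sample_rate = 10000) {
  stopifnot(inherits(clean, "temperature_trace"), inherits(noise, "noise_model"))
  t_hi <- seq(clean$time_s[1], clean$time_s[nrow(clean)], by = 1 / sample_rate)
  x <- stats::approx(clean$time_s, clean$T_probe_C, xout = t_hi)$y
  set.seed(noise$seed)
  if (noise$gaussian_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, noise$gaussian_sd)
  }
  if (length(noise$tone_freqs)) {
    phases <- stats::runif(length(noise$tone_freqs), 0, 2 * pi)
    for (i in seq_along(noise$tone_freqs)) {
      x <- x + noise$tone_amps[i] *
        sin(2 * pi * noise$tone_freqs[i] * t_hi + phases[i])
    }
  }
  raw_signal(x + noise$dc_offset, sample_rate)
}

#' Analytic Butterworth attenuation
#'
#' Magnitude response of the ideal analog Butterworth low-pass,
#' `|H(f)| = 1 / sqrt(1 + (f/fc)^(2 order))`, returned as attenuation in dB
#' (positive numbers = loss). One decade above cutoff a 4-pole filter
#' attenuates by `10 log10(1 + 10^8) = 80.0 dB`.
#'
#' @param f frequency, Hz.
#' @param spec a [filter_spec()].
#' @return Attenuation in dB.
#' @export
butterworth_attenuation_db <- function(f, spec = filter_spec()) {
  10 * log10(1 + (f / spec$cutoff)^(2 * spec$order))
}

#' Apply the causal digital Butterworth low-pass
#'
#' Bilinear-transform IIR design applied forward-only (the physical
#' controller is causal, so zero-phase filtering would be unrealistic). The
#' digital response matches the analog magnitude at the cutoff (-3.01 dB)
#' exactly; far above cutoff frequency warping makes the digital stopband
#' slightly *more* attenuating than the analog formula.
#'
#' @param raw a [raw_signal()].
#' @param spec a [filter_spec()]; cutoff must be below Nyquist.
#' @return A filtered [raw_signal()].
#' @export
butterworth_lowpass <- function(raw, spec = filter_spec()) {
  stopifnot(inherits(raw, "raw_signal"), inherits(spec, "filter_spec"))
  nyq <- raw$sample_rate / 2
  if (spec$cutoff >= nyq) {
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 spec$cutoff, nyq))
  }
  bf <- signal::butter(spec$order, spec$cutoff / nyq, type = "low")
  # warm the filter up on a pad of the first value so the causal transient
  # from zero initial conditions does not contaminate the record
  n_pad <- ceiling(raw$sample_rate / spec$cutoff) * 10L
  x <- c(rep(raw$values[1], n_pad), raw$values)
  y <- as.numeric(signal::filter(bf, x))[-seq_len(n_pad)]
  raw_signal(y, raw$sample_rate)
}

#' Block-averaging decimation
#'
#' Averages consecutive blocks (1000 samples per 100 ms by default),
#' truncating any incomplete tail block. On white noise the variance of
#' each output sample drops by the block length (a 30 dB SNR gain for
#' 1000-sample blocks).
#'
#' @param raw a [raw_signal()].
#' @param block samples per block.
#' @param t0 time of the first raw sample, seconds.
#' @return A [temperature_trace()] at `sample_rate / block` Hz; each output
#'   sample is stamped at the end of its block.
#' @export
block_average <- function(raw, block = 1000, t0 = 0) {
  stopifnot(inherits(raw, "raw_signal"), block >= 1)
  n_blocks <- floor(length(raw$values) / block)
  if (n_blocks < 1) stop("signal shorter than one averaging block")
  m <- matrix(raw$values[seq_len(n_blocks * block)], nrow = block)
  interval <- block / raw$sample_rate
  temperature_trace(t0 + seq_len(n_blocks) * interval, colMeans(m))
}

#' Signal-to-noise ratio in dB
#'
#' `10 log10(P_signal / P_noise)`, where the noise power is estimated from
#' the residual after a moving-mean detrend and the signal power from the
#' retained trend (mean square). Half a detrend window is trimmed from each
#' end before measuring. Zero noise power returns `Inf`.
#'
#' @param x a [raw_signal()], [temperature_trace()], or numeric vector.
#' @param sample_rate sampling rate, Hz (taken from the object when
#'   available).
#' @param detrend_window_s moving-mean window, seconds.
#' @return SNR in dB (possibly `Inf`).
#' @export
snr_db <- function(x, sample_rate = NULL, detrend_window_s = 1) {
  if (inherits(x, "raw_signal")) {
    v <- x$values; fs <- x$sample_rate
  } else if (inherits(x, "temperature_trace")) {
    v <- x$T_probe_C; fs <- 1 / trace_dt(x)
  } else {
    v <- x
    if (is.null(sample_rate)) stop("sample_rate required for a plain vector")
    fs <- sample_rate
  }
  w <- max(3L, round(detrend_window_s * fs))
  if (length(v) < 2 * w) stop("signal shorter than two detrend windows")
  trend <- moving_average(v, w)
  half <- floor(w / 2)
  keep <- seq.int(half + 1L, length(v) - half) # full-window region only
  p_sig <- mean(trend[keep]^2)
  p_noise <- mean((v[keep] - trend[keep])^2)
  # residual at the level of float rounding is noise-free in any physical sense
  if (p_noise <= p_sig * 1e-24) return(Inf)
  10 * log10(p_sig / p_noise)
}

#' Full sensor signal chain
#'
#' Convenience wrapper reproducing the deployed processing order: causal
#' Butterworth low-pass, then block averaging down to the 100 ms control
#' interval.
#'
#' @param raw a [raw_signal()].
#' @param spec a [filter_spec()].
#' @param block samples per averaging block.
#' @param t0 time of the first raw sample, seconds.
#' @return A [temperature_trace()] at the control rate.
#' @export
process_sensor_chain <- function(raw, spec = filter_spec(), block = 1000,
                                 t0 = 0) {
  block_average(butterworth_lowpass(raw, spec), block = block, t0 = t0)
}
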