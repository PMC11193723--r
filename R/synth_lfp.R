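# Synthetic local-field-potential traces: an amplitude-modulated
# gamma-band sinusoid (slow random envelope) over a 1/f^alpha background,
# with known ground truth for the spectral pipeline.

#' Specification of a synthetic LFP trace
#'
#' @param duration_s Trace duration, s.
#' @param sample_rate_hz Sampling rate (default 10 kHz).
#' @param osc_freq_hz Gamma-band center frequency, Hz.
#' @param osc_amp_mv Oscillation amplitude, mV (0 disables).
#' @param noise_exponent Background spectral slope alpha of 1/f^alpha.
#' @param noise_amp_mv Background standard deviation, mV.
#' @param envelope_bw_hz Bandwidth of the slow random amplitude
#'   envelope, Hz (sets the spectral peak's width).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return List of class `lfp_spec`.
#' @export
lfp_spec <- function(duration_s, sample_rate_hz = 10000, osc_freq_hz = 40,
                     osc_amp_mv = 0.1, noise_exponent = 1,
                     noise_amp_mv = 0.02, envelope_bw_hz = 4, seed = 1) {
  check_scalar(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_scalar(sample_rate_hz, "sample_rate_hz", lower = 0,
               strict_lower = TRUE)
  check_scalar(osc_freq_hz, "osc_freq_hz", lower = 0, strict_lower = TRUE)
  if (sample_rate_hz <= 2 * osc_freq_hz)
    stop_field("sample_rate_hz", "must exceed twice osc_freq_hz")
  check_scalar(osc_amp_mv, "osc_amp_mv", lower = 0)
  check_scalar(noise_amp_mv, "noise_amp_mv", lower = 0)
  check_scalar(noise_exponent, "noise_exponent", lower = 0)
  check_scalar(envelope_bw_hz, "envelope_bw_hz", lower = 0,
               strict_lower = TRUE)
  check_count(seed, "seed")
  structure(list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 osc_freq_hz = osc_freq_hz, osc_amp_mv = osc_amp_mv,
                 noise_exponent = noise_exponent,
                 noise_amp_mv = noise_amp_mv,
                 envelope_bw_hz = envelope_bw_hz, seed = seed),
            class = "lfp_spec")
}

#' Generate a synthetic LFP trace
#'
#' The gamma component is an amplitude-modulated sinusoid: a slow random
#' envelope (low-pass-filtered Gaussian noise of bandwidth
#' `envelope_bw_hz`, mean 1) multiplying a sinusoid at `osc_freq_hz`.
#' The background is spectrally shaped white noise with power density
#' proportional to 1/f^alpha. Identical specs (including seed) give
#' bitwise-identical traces; global RNG state is untouched.
#'
#' @param spec An [lfp_spec()].
#' @return An [lfp_trace()].
#' @export
#' @examples
#' tr <- gen_lfp(lfp_spec(2, osc_freq_hz = 40, seed = 7))
#' ps <- welch_psd(tr)
#' ps$freqs[which.max(ps$psd)]  # ~40 Hz
gen_lfp <- function(spec) {
  if (!inherits(spec, "lfp_spec")) spec <- do.call(lfp_spec, spec)
  n <- round(spec$duration_s * spec$sample_rate_hz)
  fs <- spec$sample_rate_hz
  with_private_seed(spec$seed, {
    t <- (seq_len(n) - 1) / fs
    x <- numeric(n)
    if (spec$osc_amp_mv > 0) {
      phase <- runif(1, 0, 2 * pi)
      bf <- signal::butter(2, min(spec$envelope_bw_hz / (fs / 2), 0.99))
      env_raw <- signal::filtfilt(bf, rnorm(n))
      sd_raw <- sd(env_raw)
      env <- if (sd_raw > 0) 1 + 0.3 * env_raw / sd_raw else rep(1, n)
      env <- pmax(env, 0.05)
      x <- x + spec$osc_amp_mv * env * sin(2 * pi * spec$osc_freq_hz * t +
                                             phase)
    }
    if (spec$noise_amp_mv > 0) {
      w <- rnorm(n)
      W <- fft(w)
      freqs <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
      shape <- c(0, abs(freqs[-1])^(-spec$noise_exponent / 2))
      z <- Re(fft(W * shape, inverse = TRUE)) / n
      z_sd <- sd(z)
      if (z_sd > 0) x <- x + spec$noise_amp_mv * z / z_sd
    }
    lfp_trace(x, fs)
  })
}
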