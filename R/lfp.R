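# Gamma-oscillation characterization of local-field-potential traces:
# zero-phase low-pass filtering, Welch power spectral density, spectral
# peak features, oscillation classification and paired substrate-switch
# comparison.

#' Construct an LFP trace
#'
#' @param samples Numeric vector, mV.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param t0_s Recording-clock time of the first sample, s.
#' @return List of class `lfp_trace`.
#' @export
lfp_trace <- function(samples, sample_rate_hz, t0_s = 0) {
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop_field("samples", "must be finite numeric")
  check_scalar(sample_rate_hz, "sample_rate_hz", lower = 0,
               strict_lower = TRUE)
  check_scalar(t0_s, "t0_s")
  structure(list(samples = as.numeric(samples),
                 sample_rate_hz = sample_rate_hz, t0_s = t0_s),
            class = "lfp_trace")
}

#' Zero-phase 200 Hz Butterworth low-pass
#'
#' Order-4 digital Butterworth low-pass with 200 Hz corner, applied
#' forward and backward (`signal::filtfilt`) for zero phase shift and
#' unit DC gain.
#'
#' @param trace An [lfp_trace()] sampled above 400 Hz.
#' @return Filtered [lfp_trace()].
#' @export
lowpass_200 <- function(trace) {
  fs <- trace$sample_rate_hz
  if (fs <= 400)
    stop("sample rate must exceed 400 Hz for a 200 Hz corner", call. = FALSE)
  # filtfilt needs ~3x filter order of warm-up samples on each end
  if (length(trace$samples) < 50)
    stop("trace too short for filter warm-up", call. = FALSE)
  bf <- signal::butter(4, 200 / (fs / 2), type = "low")
  # odd-reflection padding suppresses the zero-initial-condition edge
  # transients of the forward-backward pass
  x <- trace$samples
  n <- length(x)
  np <- min(1000L, n - 1L)
  left <- 2 * x[1] - x[rev(seq_len(np) + 1L)]
  right <- 2 * x[n] - x[rev(n - seq_len(np))]
  y <- signal::filtfilt(bf, c(left, x, right))
  lfp_trace(y[np + seq_len(n)], fs, trace$t0_s)
}

#' Welch power spectral density
#'
#' Averaged periodogram over Hamming-windowed segments with 50% overlap
#' and per-segment mean detrending. One-sided density normalization:
#' the integral of the PSD over frequency recovers the trace variance
#' (Parseval), so a unit-amplitude sinusoid carries integrated power 0.5.
#'
#' @param trace An [lfp_trace()].
#' @param segment_len Segment (window) length in samples; the frequency
#'   bin width is `sample_rate_hz / segment_len` (1.2207 Hz for 10 kHz
#'   traces with the default 8192-point window).
#' @return List of class `power_spectrum`: `freqs` (Hz), `psd`
#'   (mV^2/Hz), `bin_width_hz`, `segment_len`, `window = "hamming"`,
#'   `n_segments`.
#' @export
#' @examples
#' tr <- lfp_trace(sin(2 * pi * 40 * seq(0, 2, by = 1e-4)), 1e4)
#' ps <- welch_psd(tr)
#' ps$bin_width_hz            # 1.2207
#' ps$freqs[which.max(ps$psd)] # ~40 Hz
welch_psd <- function(trace, segment_len = 8192) {
  segment_len <- check_count(segment_len, "segment_len", lower = 8)
  x <- trace$samples
  fs <- trace$sample_rate_hz
  if (length(x) < segment_len)
    stop("trace shorter than one Welch segment", call. = FALSE)
  w <- signal::hamming(segment_len)
  step <- segment_len %/% 2
  starts <- seq(1, length(x) - segment_len + 1, by = step)
  nfreq <- segment_len %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + segment_len - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg)[seq_len(nfreq)])^2
    acc <- acc + sp
  }
  scale <- 1 / (fs * sum(w^2))
  psd <- acc / length(starts) * scale
  # one-sided: double all bins except DC (and Nyquist for even lengths)
  psd[2:(nfreq - 1)] <- 2 * psd[2:(nfreq - 1)]
  if (segment_len %% 2 != 0) psd[nfreq] <- 2 * psd[nfreq]
  freqs <- (seq_len(nfreq) - 1) * fs / segment_len
  structure(list(freqs = freqs, psd = psd,
                 bin_width_hz = fs / segment_len,
                 segment_len = segment_len, window = "hamming",
                 n_segments = length(starts)),
            class = "power_spectrum")
}

#' Spectral peak features in a search band
#'
#' Locates the PSD maximum inside `search_band` and measures peak
#' frequency, peak power and the full width at half-maximum of the
#' contiguous region around the peak, with linear interpolation at the
#' two half-maximum crossings. Ties resolve to the lower frequency. If a
#' half-maximum crossing is not reached inside the band, the band-limited
#' width is reported and the result is flagged degenerate.
#'
#' @param spectrum A [welch_psd()] result.
#' @param search_band Two-element Hz range (default 20-100 Hz, wide
#'   enough that sub-gamma peaks remain measurable but classifiable).
#' @return List of class `gamma_features`: `peak_freq_hz`, `peak_power`
#'   (mV^2/Hz), `fwhm_hz`, `is_gamma` (NA until [classify_gamma()]),
#'   `degenerate` flag.
#' @export
extract_features <- function(spectrum, search_band = c(20, 100)) {
  if (length(search_band) != 2 || search_band[1] >= search_band[2])
    stop_field("search_band", "must be an increasing (lo, hi) pair")
  idx <- which(spectrum$freqs >= search_band[1] &
                 spectrum$freqs <= search_band[2])
  if (!length(idx))
    stop("search band contains no frequency bins", call. = FALSE)
  f <- spectrum$freqs[idx]
  p <- spectrum$psd[idx]
  ipk <- which.max(p)  # which.max takes the first (lowest-frequency) tie
  half <- p[ipk] / 2
  degenerate <- FALSE

  # walk left from the peak to the half-maximum crossing
  li <- ipk
  while (li > 1 && p[li - 1] >= half) li <- li - 1
  if (li == 1 && p[1] >= half) {
    f_lo <- f[1]; degenerate <- TRUE
  } else {
    f_lo <- f[li - 1] + (half - p[li - 1]) / (p[li] - p[li - 1]) *
      (f[li] - f[li - 1])
  }
  ri <- ipk
  while (ri < length(p) && p[ri + 1] >= half) ri <- ri + 1
  if (ri == length(p) && p[length(p)] >= half) {
    f_hi <- f[length(p)]; degenerate <- TRUE
  } else {
    f_hi <- f[ri] + (p[ri] - half) / (p[ri] - p[ri + 1]) *
      (f[ri + 1] - f[ri])
  }
  structure(list(peak_freq_hz = f[ipk], peak_power = p[ipk],
                 fwhm_hz = f_hi - f_lo, is_gamma = NA,
                 degenerate = degenerate),
            class = "gamma_features")
}

#' Gamma-oscillation classification
#'
#' An activity pattern counts as a gamma oscillation when the spectral
#' peak frequency exceeds 24 Hz (recordings at 34 +/- 1 degC) and the
#' peak power exceeds 1e-4 mV^2/Hz.
#'
#' @param features A [extract_features()] result.
#' @param freq_min_hz,power_min Classification thresholds.
#' @return `TRUE`/`FALSE`.
#' @export
#' @examples
#' f <- structure(list(peak_freq_hz = 40, peak_power = 1e-3),
#'                class = "gamma_features")
#' classify_gamma(f)  # TRUE
classify_gamma <- function(features, freq_min_hz = 24, power_min = 1e-4) {
  if (!is.finite(features$peak_freq_hz) || !is.finite(features$peak_power))
    stop("non-finite features", call. = FALSE)
  features$peak_freq_hz > freq_min_hz && features$peak_power > power_min
}

#' Extract a time segment from a trace
#'
#' @param trace An [lfp_trace()].
#' @param start_s Segment start on the recording clock, s.
#' @param len_s Segment length, s (> 0).
#' @return The sub-trace with updated `t0_s`.
#' @export
segment <- function(trace, start_s, len_s) {
  check_scalar(start_s, "start_s")
  check_scalar(len_s, "len_s", lower = 0, strict_lower = TRUE)
  fs <- trace$sample_rate_hz
  i0 <- round((start_s - trace$t0_s) * fs) + 1
  n <- round(len_s * fs)
  if (i0 < 1 || i0 + n - 1 > length(trace$samples))
    stop("segment window lies outside the recording", call. = FALSE)
  lfp_trace(trace$samples[i0:(i0 + n - 1)], fs, start_s)
}

# Full single-trace analysis chain: low-pass, Welch, features, class.
analyze_trace <- function(trace, segment_len = 8192,
                          search_band = c(20, 100)) {
  ps <- welch_psd(lowpass_200(trace), segment_len)
  ft <- extract_features(ps, search_band)
  ft$is_gamma <- classify_gamma(ft)
  ft
}

#' Paired pre/post comparison of two recordings
#'
#' Characterizes two segments of the same slice (e.g. glucose-only vs
#' glucose + lactate recording solution) and reports per-feature fold
#' changes post/pre. Traces failing gamma classification yield a flagged
#' result to be excluded from cohort statistics.
#'
#' @param pre,post [lfp_trace()] objects.
#' @param segment_len Welch window, samples.
#' @return List of class `paired_result`: `pre`, `post` (features),
#'   `fold_change` (named: peak_freq_hz, peak_power, fwhm_hz), `valid`.
#' @export
paired_compare <- function(pre, post, segment_len = 8192) {
  fpre <- analyze_trace(pre, segment_len)
  fpost <- analyze_trace(post, segment_len)
  valid <- isTRUE(fpre$is_gamma) && isTRUE(fpost$is_gamma)
  fc <- c(peak_freq_hz = fpost$peak_freq_hz / fpre$peak_freq_hz,
          peak_power = fpost$peak_power / fpre$peak_power,
          fwhm_hz = fpost$fwhm_hz / fpre$fwhm_hz)
  structure(list(pre = fpre, post = fpost, fold_change = fc,
                 valid = valid),
            class = "paired_result")
}

#' Paired t test over a cohort of pre/post results
#'
#' Thin harness around [stats::t.test()] on one spectral feature across
#' slices; invalid (non-gamma) pairs are dropped.
#'
#' @param results List of [paired_compare()] results.
#' @param feature `"peak_freq_hz"`, `"peak_power"` or `"fwhm_hz"`.
#' @return The `htest` object.
#' @export
cohort_paired_t <- function(results, feature = c("peak_freq_hz",
                                                 "peak_power", "fwhm_hz")) {
  feature <- match.arg(feature)
  results <- Filter(function(r) isTRUE(r$valid), results)
  if (length(results) < 3)
    stop("need at least 3 valid pairs", call. = FALSE)
  pre <- vapply(results, function(r) r$pre[[feature]], numeric(1))
  post <- vapply(results, function(r) r$post[[feature]], numeric(1))
  t.test(post, pre, paired = TRUE)
}
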