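# Spectral pipeline: filtering, Welch PSD, peak features,
# classification, segmentation, paired comparison.

fs <- 10000
tt <- function(dur) seq(0, dur - 1 / fs, by = 1 / fs)

test_that("the 200 Hz low-pass preserves the passband and kills the stopband", {
  tr40 <- lfp_trace(sin(2 * pi * 40 * tt(2)), fs)
  out40 <- lowpass_200(tr40)
  mid <- 5000:15000
  expect_equal(max(abs(out40$samples[mid])), 1, tolerance = 0.01)

  tr1k <- lfp_trace(sin(2 * pi * 1000 * tt(2)), fs)
  out1k <- lowpass_200(tr1k)
  expect_lt(max(abs(out1k$samples[mid])), 0.1)  # > 90% attenuation

  trdc <- lfp_trace(rep(0.7, fs), fs)
  expect_equal(lowpass_200(trdc)$samples, rep(0.7, fs), tolerance = 1e-9)

  expect_error(lowpass_200(lfp_trace(1:10, fs)), "short")
  expect_error(lowpass_200(lfp_trace(rnorm(1000), 300)), "400 Hz")
})

test_that("Welch frequency axis is exact and the density obeys Parseval", {
  for (sl in c(4096, 8192)) {
    for (f0 in c(2000, 10000)) {
      ps <- welch_psd(lfp_trace(rnorm(3 * sl), f0), segment_len = sl)
      expect_identical(ps$freqs[2] - ps$freqs[1], f0 / sl)
      expect_identical(ps$bin_width_hz, f0 / sl)
    }
  }
  # 10 kHz with the 8192-point window: the printed 1.2207 Hz bin
  ps <- welch_psd(lfp_trace(rnorm(20000), fs), 8192)
  expect_equal(ps$bin_width_hz, 1.2207, tolerance = 1e-4)

  set.seed(5)
  wn <- lfp_trace(rnorm(5e4, sd = 0.4), fs)
  psw <- welch_psd(wn)
  expect_equal(sum(psw$psd) * psw$bin_width_hz, 0.16, tolerance = 0.05)

  pure <- welch_psd(lfp_trace(sin(2 * pi * 40 * tt(2)), fs))
  expect_lt(abs(pure$freqs[which.max(pure$psd)] - 40), pure$bin_width_hz)
  # unit-amplitude sinusoid: integrated peak power ~ 0.5 mV^2
  band <- pure$freqs > 35 & pure$freqs < 45
  expect_equal(sum(pure$psd[band]) * pure$bin_width_hz, 0.5,
               tolerance = 0.05)

  expect_error(welch_psd(lfp_trace(rnorm(100), fs), 8192), "shorter")
})

test_that("feature extraction recovers a Lorentzian's width and documents ties", {
  freqs <- seq(0, 200, by = 0.5)
  gam <- 4  # half-width at half-maximum
  psd <- 1e-3 / (1 + ((freqs - 60) / gam)^2)
  sp <- structure(list(freqs = freqs, psd = psd, bin_width_hz = 0.5,
                       segment_len = NA, window = "analytic"),
                  class = "power_spectrum")
  ft <- extract_features(sp)
  expect_equal(ft$peak_freq_hz, 60)
  expect_lt(abs(ft$fwhm_hz - 2 * gam), 0.5)  # within one bin of 2*gamma

  flat <- structure(list(freqs = freqs, psd = rep(1, length(freqs)),
                         bin_width_hz = 0.5, segment_len = NA,
                         window = "analytic"),
                    class = "power_spectrum")
  ff <- extract_features(flat, c(20, 100))
  expect_true(ff$degenerate)
  expect_equal(ff$fwhm_hz, 80)

  two <- psd + 1e-3 / (1 + ((freqs - 90) / gam)^2)
  sp2 <- structure(list(freqs = freqs, psd = two, bin_width_hz = 0.5),
                   class = "power_spectrum")
  expect_equal(extract_features(sp2)$peak_freq_hz, 60)  # lower-freq tie-break

  expect_error(extract_features(sp, c(300, 400)), "no frequency bins")
})

test_that("gamma classification applies both printed thresholds", {
  f <- function(fr, pw) structure(list(peak_freq_hz = fr, peak_power = pw),
                                  class = "gamma_features")
  expect_true(classify_gamma(f(40, 1e-3)))
  expect_false(classify_gamma(f(10, 1.0)))
  expect_false(classify_gamma(f(40, 1e-5)))
})

test_that("segmentation arithmetic and bounds are exact", {
  tr <- lfp_trace(rnorm(50 * fs), fs)   # 50 s record
  seg <- segment(tr, 10, 3)
  expect_equal(length(seg$samples), 3 * fs)
  expect_equal(seg$t0_s, 10)
  expect_identical(segment(tr, 0, 50)$samples, tr$samples)
  expect_error(segment(tr, 0, 0), "len_s")
  expect_error(segment(tr, 49, 5), "outside")
})

test_that("scale equivariance: amplitude scaling squares the power only", {
  tr <- gen_lfp(lfp_spec(2, seed = 31))
  f1 <- welch_psd(tr) |> extract_features()
  tr3 <- lfp_trace(3 * tr$samples, fs)
  f3 <- welch_psd(tr3) |> extract_features()
  expect_equal(f3$peak_power / f1$peak_power, 9, tolerance = 1e-9)
  expect_identical(f3$peak_freq_hz, f1$peak_freq_hz)
  expect_equal(f3$fwhm_hz, f1$fwhm_hz, tolerance = 1e-9)
})

test_that("paired comparison reports unit and quadrupled fold changes", {
  tr <- gen_lfp(lfp_spec(2, seed = 41))
  same <- paired_compare(tr, tr)
  expect_true(same$valid)
  expect_equal(unname(same$fold_change), c(1, 1, 1))

  doubled <- paired_compare(tr, lfp_trace(2 * tr$samples, fs))
  expect_equal(unname(doubled$fold_change[["peak_power"]]), 4,
               tolerance = 1e-9)
})

test_that("the paired t harness is calibrated under the null", {
  pvals <- vapply(1:20, function(s) {
    res <- lapply(1:6, function(i) {
      pre <- gen_lfp(lfp_spec(1.5, seed = 1000 * s + i))
      post <- gen_lfp(lfp_spec(1.5, seed = 5000 * s + i))
      paired_compare(pre, post)
    })
    cohort_paired_t(res, "peak_power")$p.value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("synthetic gamma is recovered across many seeds", {
  for (s in 1:25) {
    ft <- neuroenergetics:::analyze_trace(gen_lfp(lfp_spec(1.5, seed = s)))
    expect_true(ft$is_gamma)
    expect_lte(abs(ft$peak_freq_hz - 40), 10000 / 8192)
  }
})
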