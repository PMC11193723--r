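# Generators: determinism, ground-truth recoverability, noise scaling.

test_that("every generator is a pure function of its spec and seed", {
  expect_identical(gen_lfp(lfp_spec(1, seed = 3))$samples,
                   gen_lfp(lfp_spec(1, seed = 3))$samples)
  expect_identical(gen_plate(plate_spec("lactate", 1000, noise_sd = 0.01,
                                        seed = 5)),
                   gen_plate(plate_spec("lactate", 1000, noise_sd = 0.01,
                                        seed = 5)))
  d <- ct_design(c("IL6", "ACTB"), ct_noise_sd = 0.2, seed = 9)
  expect_identical(gen_ct_table(d), gen_ct_table(d))
  sp <- image_spec(n_microglia = 3, n_other_nuclei = 2, seed = 4)
  expect_identical(gen_image_stack(sp)$stack, gen_image_stack(sp)$stack)
  op <- o2_profile_spec(8, noise_sd = 3, seed = 2)
  expect_identical(gen_o2_profile(op), gen_o2_profile(op))
})

test_that("generators leave the global RNG stream untouched", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(gen_lfp(lfp_spec(0.5, seed = 77)))
  invisible(gen_plate(plate_spec("lactate", 100, seed = 77)))
  expect_identical(runif(1), a)
})

test_that("noiseless LFP carries its planted frequency; no oscillation means no gamma", {
  tr <- gen_lfp(lfp_spec(2, osc_freq_hz = 40, noise_amp_mv = 0, seed = 1))
  ps <- welch_psd(tr)
  expect_lt(abs(ps$freqs[which.max(ps$psd)] - 40), ps$bin_width_hz)

  # pure 1/f background stays under the gamma power threshold
  tr0 <- gen_lfp(lfp_spec(2, osc_amp_mv = 0, noise_amp_mv = 0.02,
                          seed = 2))
  ft0 <- extract_features(welch_psd(tr0))
  expect_false(classify_gamma(ft0))
})

test_that("lfp spec validation names the offending field", {
  expect_error(lfp_spec(-1), "duration_s")
  expect_error(lfp_spec(1, sample_rate_hz = 60, osc_freq_hz = 40),
               "sample_rate_hz")
  expect_error(lfp_spec(1, osc_amp_mv = -0.1), "osc_amp_mv")
})

test_that("plate standards follow the dilution series; noiseless fits recover truth", {
  pd <- gen_plate(plate_spec("IL6_ELISA", 8000, n_standards = 8,
                             curve_truth = c(0.04, 2e-4), noise_sd = 0))
  expect_equal(unique(pd$conc[pd$role == "standard"]),
               c(8000, 4000, 2000, 1000, 500, 250, 125, 62.5))
  pd2 <- gen_plate(plate_spec("griess_nitrite", 80, n_standards = 9,
                              noise_sd = 0))
  expect_equal(min(pd2$conc, na.rm = TRUE), 0.3125)
  cv <- fit_standard_curve(pd[pd$role == "standard", ], "linear")
  expect_equal(cv$coefficients, c(0.04, 2e-4), tolerance = 1e-10)
})

test_that("null and planted Ct designs reproduce their fold changes", {
  genes <- c("IL6", "ACTB")
  e0 <- ddct_expression(gen_ct_table(ct_design(genes)))
  expect_true(all(abs(e0$values - 1) < 1e-12))

  eff <- matrix(0, 2, 6, dimnames = list(genes, NULL))
  eff["IL6", 2] <- 3  # LPS group
  e <- ddct_expression(gen_ct_table(ct_design(genes, effect_logfc = eff)))
  expect_equal(unname(e$values["IL6", e$groups == "LPS"]), rep(8, 3))
  # resolution pattern: RES96 back at baseline by construction
  d <- ct_design(c("IL6", "TNF", "ACTB"),
                 effect_logfc = inflammation_effects(c("IL6", "TNF",
                                                       "ACTB")))
  er <- ddct_expression(gen_ct_table(d))
  expect_equal(unname(er$values[, er$groups == "RES96"]),
               matrix(1, 2, 3), tolerance = 1e-12)
  expect_error(ct_design(c("IL6", "TNF")), "reference gene")
})

test_that("image stacks carry recoverable ground truth", {
  out <- gen_image_stack(image_spec(n_microglia = 10, n_other_nuclei = 0,
                                    noise_sd = 0, background_level = 0,
                                    seed = 21))
  expect_equal(count_microglia(out$stack)$count, 10)
  out0 <- gen_image_stack(image_spec(n_microglia = 0, n_other_nuclei = 8,
                                     noise_sd = 0, seed = 22))
  expect_equal(count_microglia(out0$stack)$count, 0)
  expect_error(gen_image_stack(image_spec(shape = c(100, 100),
                                          n_microglia = 40,
                                          soma_radius_px = 10,
                                          arm_length_px = 5)),
               "overcrowded|too small")
})

test_that("o2 profiles plant their core and span the probe geometry", {
  pr <- gen_o2_profile(o2_profile_spec(6, core_step_index = 4,
                                       noise_sd = 0))
  expect_equal(locate_slice_core(pr)$core_index, 4)
  expect_equal(max(pr$depth_um), 6 * 20 * sin(55 * pi / 180),
               tolerance = 1e-12)  # ~98.3 um
  flat <- gen_o2_profile(o2_profile_spec(5, surface_conc = 100,
                                         core_conc = 100, noise_sd = 0))
  loc <- locate_slice_core(flat)
  expect_equal(loc$core_index, 1)
  expect_equal(loc$flag, "tie")
})

test_that("estimator error grows with planted noise (plate unknowns)", {
  med_err <- vapply(c(0.002, 0.02, 0.08), function(ns) {
    errs <- vapply(1:20, function(s) {
      pd <- gen_plate(plate_spec("lactate", 1000, n_standards = 6,
                                 curve_truth = c(0.05, 1e-3),
                                 noise_sd = ns,
                                 unknowns_truth = c(120, 450), seed = s))
      cv <- fit_standard_curve(pd[pd$role == "standard", ], "linear")
      rec <- tryCatch(
        concentration_from_signal(cv, pd$signal[pd$role == "unknown"]),
        error = function(e) c(NA, NA))
      median(abs(rec - c(120, 450)), na.rm = TRUE)
    }, numeric(1))
    median(errs, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_err) > 0))
})
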