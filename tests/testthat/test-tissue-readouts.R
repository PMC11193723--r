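# Bench-data reductions: dilutions, standard curves, sensor calibration,
# probe geometry, comparative Ct, normalization and heatmap z-scores.

test_that("dilution series reproduce the printed assay ladders", {
  expect_equal(dilution_series(8000, 2, 8),
               c(8000, 4000, 2000, 1000, 500, 250, 125, 62.5))
  expect_equal(dilution_series(80, 2, 9)[9], 0.3125)
  expect_equal(dilution_series(1000, 2, 6),
               c(1000, 500, 250, 125, 62.5, 31.25))
})

test_that("standard curves fit exactly on noiseless data and refuse bad input", {
  conc <- dilution_series(1000, 2, 6)
  lin <- data.frame(conc = conc, signal = 0.03 + 2e-3 * conc)
  cl <- fit_standard_curve(lin, "linear")
  expect_equal(cl$coefficients, c(0.03, 2e-3), tolerance = 1e-12)

  quad <- data.frame(conc = conc, signal = 0.05 + 4e-4 * conc -
                       5e-8 * conc^2)
  cq <- fit_standard_curve(quad, "quadratic")
  expect_equal(cq$coefficients, c(0.05, 4e-4, -5e-8), tolerance = 1e-9)

  expect_error(fit_standard_curve(quad[1:2, ], "quadratic"), "at least")
  bumpy <- data.frame(conc = c(0, 1, 2, 3, 4),
                      signal = c(0, 1, 0.2, 1.1, 0.1))
  expect_error(fit_standard_curve(bumpy, "quadratic"), "monotone")
})

test_that("curve inversion round-trips, respects dilution, rejects range", {
  conc <- dilution_series(8000, 2, 8)
  cq <- fit_standard_curve(
    data.frame(conc = conc, signal = 0.05 + 4e-4 * conc - 2e-8 * conc^2),
    "quadratic")
  targets <- c(100, 500, 3000, 8000)
  sig <- 0.05 + 4e-4 * targets - 2e-8 * targets^2
  rec <- concentration_from_signal(cq, sig)
  expect_equal(rec, targets, tolerance = 1e-6)
  # endpoint identity at the top standard
  expect_equal(concentration_from_signal(cq, max(cq$signal_range)), 8000,
               tolerance = 1e-6)

  cl <- fit_standard_curve(
    data.frame(conc = dilution_series(1000, 2, 6),
               signal = 0.02 + 1e-3 * dilution_series(1000, 2, 6)),
    "linear")
  expect_equal(concentration_from_signal(cl, 0.02 + 1e-3 * 100,
                                         dilution_factor = 5), 500,
               tolerance = 1e-9)
  expect_error(concentration_from_signal(cl, 10), "extrapolate")
})

test_that("sensor calibration anchors zero, reports r2 and flags drift", {
  pts <- data.frame(o2_fraction = c(0, 20, 95),
                    raw_signal = c(0.5, 2.5, 10))
  # a perfectly linear sensor: signal = 0.5 + 0.1 * fraction
  pts$raw_signal <- 0.5 + 0.1 * pts$o2_fraction
  cal <- calibrate_o2(pts)
  expect_equal(cal$r2, 1)
  expect_equal(apply_calibration(cal, 0.5), 0, tolerance = 1e-9)

  noisy <- data.frame(o2_fraction = c(0, 20, 95),
                      raw_signal = c(1.4, 1.5, 9))
  expect_warning(calibrate_o2(noisy), "r\\^2")
  expect_error(calibrate_o2(data.frame(o2_fraction = c(0, 0, 95),
                                       raw_signal = 1:3)), "duplicate")

  drift <- calibration_drift(cal, calibrate_o2(transform(
    pts, raw_signal = 0.5 + 0.115 * o2_fraction)))
  expect_true(drift$drift)  # 15% slope change against 10.87% mapped limit
  nodrift <- calibration_drift(cal, cal)
  expect_false(nodrift$drift)
})

test_that("probe geometry matches the printed step depth", {
  expect_equal(depth_axis(1), 20 * sin(55 * pi / 180), tolerance = 1e-12)
  expect_equal(round(depth_axis(1)), 16)  # the printed ~16 um
  expect_equal(max(depth_axis(6)), 98.3, tolerance = 0.05)
  expect_equal(depth_axis(3, 10, 90), c(10, 20, 30))
  expect_error(depth_axis(3, 10, 0), "angle_deg")
  expect_error(depth_axis(3, 10, 120), "angle_deg")
})

test_that("slice-core localization handles minima, boundaries and ties", {
  prof <- function(v) data.frame(concentration = v)
  expect_equal(locate_slice_core(prof(c(150, 120, 100, 90, 95)))$core_index,
               4)
  mono <- locate_slice_core(prof(c(150, 120, 100, 90)))
  expect_equal(mono$core_index, 4)
  expect_equal(mono$flag, "boundary")
  flat <- locate_slice_core(prof(rep(80, 5)))
  expect_equal(flat$core_index, 1)
  expect_equal(flat$flag, "tie")
})

test_that("comparative Ct quantification obeys its identities", {
  ct <- expand.grid(sample = c("CTL_1", "CTL_2", "LPS_1", "LPS_2"),
                    gene = c("IL6", "ACTB"), stringsAsFactors = FALSE)
  ct$group <- sub("_.*", "", ct$sample)
  ct$ct <- 20
  e <- ddct_expression(ct)
  expect_true(all(e$values == 1))

  # one cycle lower in LPS, reference untouched: fold 2
  ct2 <- ct
  ct2$ct[ct2$gene == "IL6" & ct2$group == "LPS"] <- 19
  e2 <- ddct_expression(ct2)
  expect_equal(unname(e2$values["IL6", e2$groups == "LPS"]), c(2, 2))

  # per-sample loading offsets cancel
  ct3 <- ct2
  for (s in unique(ct3$sample))
    ct3$ct[ct3$sample == s] <- ct3$ct[ct3$sample == s] +
      match(s, unique(ct3$sample))
  e3 <- ddct_expression(ct3)
  expect_equal(e3$values, e2$values, tolerance = 1e-12)

  # samples lacking the reference gene are dropped with a warning
  ct4 <- ct2[!(ct2$sample == "LPS_2" & ct2$gene == "ACTB"), ]
  expect_warning(e4 <- ddct_expression(ct4), "dropping")
  expect_false("LPS_2" %in% colnames(e4$values))

  expect_error(ddct_expression(ct, reference_gene = "GAPDH"),
               "reference gene")
})

test_that("control normalization and row ratios behave as stated", {
  m <- matrix(c(2, 4, 6, 8, 1, 2, 3, 4), 2, 4, byrow = TRUE,
              dimnames = list(c("akg", "citrate"), NULL))
  groups <- c("CTL", "CTL", "LPS", "LPS")
  nm <- normalize_to_control(m, groups)
  expect_equal(rowMeans(nm[, 1:2]), c(akg = 1, citrate = 1))
  expect_equal(normalize_to_control(2 * m, groups), nm)
  expect_equal(unname(row_ratio(m, "akg", "akg")), rep(1, 4))
  expect_equal(unname(row_ratio(m, "akg", "citrate")), rep(2, 4))
  expect_error(normalize_to_control(m * 0, groups), "positive")
})

test_that("heatmap z-scores and Ward clustering satisfy their invariants", {
  set.seed(11)
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  zc <- zscore_cluster(m)
  expect_equal(unname(rowMeans(zc$z)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(zc$z, 1, sd)), rep(1, 6), tolerance = 1e-12)

  # invariance to per-row affine transforms
  m2 <- m * 7 + 3
  expect_equal(zscore_cluster(m2)$z, zc$z, tolerance = 1e-9)

  # constant rows flagged and zeroed
  m3 <- rbind(m, flatrow = 5)
  zc3 <- zscore_cluster(m3)
  expect_equal(zc3$constant_rows, "flatrow")
  expect_true(all(zc3$z["flatrow", ] == 0))

  # identical columns merge first at height zero under Ward linkage
  m4 <- cbind(m, s11 = m[, 1])
  zc4 <- zscore_cluster(m4)
  expect_equal(min(zc4$col_hclust$height), 0)
  first <- sort(abs(zc4$col_hclust$merge[1, ]))
  expect_equal(first, c(1, 11))
})
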