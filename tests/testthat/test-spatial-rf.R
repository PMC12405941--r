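test_that("extract_raw_map takes max - min per epoch (offset-invariant)", {
  proto <- grid_scan_protocol(extent_deg = 2)   # 3x3 grid, 9 epochs
  n_ep <- 9L; per <- 145L
  samples <- rep(-50, n_ep * per)               # resting potential -50 mV
  samples[4 * per + 30] <- -40                  # epoch 5 peaks at -40 mV
  mk <- data.frame(time_s = (0:8) * 0.145, kind = "flash", payload = 1:9)
  tr <- recording_trace(samples, 1000, markers = mk)
  m <- extract_raw_map(tr, proto)
  expect_equal(m$values[2, 2], 10)              # max - min, baseline-free
  expect_equal(sum(m$values), 10)               # all other epochs zero

  # flat zero trace -> all-zero map
  tr0 <- recording_trace(rep(0, n_ep * per), 1000, markers = mk)
  expect_equal(max(extract_raw_map(tr0, proto)$values), 0)

  # missing epochs are reported by position
  mk_miss <- mk[-5, ]
  tr_miss <- recording_trace(samples, 1000, markers = mk_miss)
  expect_error(extract_raw_map(tr_miss, proto), "missing epochs.*5")
})

test_that("noise-free map peaks at the true-centre grid node", {
  cell <- single_rf_cell(az = 3, el = -2, sigma = 2)
  proto <- grid_scan_protocol()
  m <- extract_raw_map(simulate_grid_scan(cell, proto, seed = 1), proto)
  idx <- which(m$values == max(m$values), arr.ind = TRUE)
  expect_equal(m$az_deg[idx[2]], 3)
  expect_equal(m$el_deg[idx[1]], -2)
})

test_that("smooth_map matches a direct convolution oracle", {
  # identity limit
  set.seed(3)
  raw <- sensitivity_map(matrix(runif(441), 21, 21), "raw")
  expect_equal(smooth_map(raw, sigma_deg = 1e-6)$values, raw$values,
               tolerance = 1e-6)
  # DC preservation: constant map is unchanged
  const <- sensitivity_map(matrix(2.5, 21, 21), "raw")
  expect_equal(smooth_map(const, 1)$values, const$values,
               tolerance = 1e-12)
  # central impulse -> separable product of the 1-D kernel (direct oracle)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- smooth_map(sensitivity_map(imp, "raw"), 1)
  r <- 4                                  # kernel radius for sigma = 1 px
  x <- (-r):r
  k1 <- exp(-x^2 / 2); k1 <- k1 / sum(k1)
  want <- outer(k1, k1)
  expect_equal(sm$values[11 + x, 11 + x], want, tolerance = 1e-12)
  expect_error(smooth_map(raw, sigma_deg = 0), "sigma")
  expect_error(smooth_map(sm, 1), "raw-stage")  # already smoothed
})

test_that("to_sensitivity applies the inverse Hill pointwise", {
  # two active positions at 0.5 and 0.9 of v_max, n = 1: sensitivities 1:9
  v <- matrix(0, 21, 21); v[11, 9] <- 20; v[11, 13] <- 36
  m <- sensitivity_map(v, "raw")
  s <- to_sensitivity(m, make_hill(v_max = 40, n = 1))
  expect_equal(max(s$values), 1)
  expect_equal(s$values[11, 9] / s$values[11, 13], 1 / 9,
               tolerance = 1e-9)
  expect_error(to_sensitivity(sensitivity_map(matrix(0, 3, 3), "raw"),
                              make_hill()), "degenerate")
})

test_that("noise-free pipeline recovers the ground-truth profile exactly", {
  cell <- single_rf_cell(az = 2, el = 1, sigma = 2.5)   # on-node centre
  sens <- scan_to_sens(cell, smooth = FALSE)
  co <- grid_coordinates(grid_scan_protocol())
  truth <- outer(co$el_deg, co$az_deg,
                 function(el, az) spatial_profile(cell, az, el))
  expect_lt(max(abs(sens$values - truth)), 1e-6)
})

test_that("fit_rf recovers single and double Gaussian components", {
  cell <- single_rf_cell(az = 1.2, el = -0.7, sigma = 2)
  rf <- fit_rf(scan_to_sens(cell, smooth = FALSE))
  expect_equal(rf$n_components, 1L)
  expect_equal(rf$components$fwhm_circ[1], FWHM_C * 2, tolerance = 0.01)
  expect_equal(rf$components$center_az[1], 1.2, tolerance = 0.05)
  expect_equal(rf$components$center_el[1], -0.7, tolerance = 0.05)
  expect_equal(rf$quality, "high")

  cell2 <- two_rf_cell(sep = 8, w2 = 0.6, sigma = 1.5)
  rf2 <- fit_rf(scan_to_sens(cell2, smooth = FALSE))
  expect_equal(rf2$n_components, 2L)
  expect_equal(rf2$components$role, c("main", "coupled"))
  expect_equal(rf2$components$weight, c(1, 0.6), tolerance = 1e-3)

  # forcing one component onto a two-peak map must fit strictly worse
  rf1 <- fit_rf(scan_to_sens(cell2, smooth = FALSE), max_components = 1)
  expect_gt(rf1$rss, rf2$rss)
})

test_that("FWHM identities hold exactly on the fitted components", {
  # elliptical component with FWHM axes 9 and 4 deg
  cellE <- ground_truth_cell(data.frame(
    az = 0, el = 0, sigma_major = 9 / FWHM_C, sigma_minor = 4 / FWHM_C,
    orientation = 25, w = 1, latency_ms = 0), noise_sd_mV = 0,
    v_max = 40, k_half = 1, n_hill = 1)
  rf <- fit_rf(scan_to_sens(cellE, smooth = FALSE))
  comp <- rf$components[1, ]
  expect_equal(comp$fwhm_major, FWHM_C * comp$sigma_major)
  expect_equal(comp$fwhm_minor, FWHM_C * comp$sigma_minor)
  expect_equal(comp$fwhm_circ,
               sqrt(comp$fwhm_major * comp$fwhm_minor))
  expect_equal(comp$fwhm_circ, 6.0, tolerance = 0.02)   # sqrt(9 * 4)
  expect_equal(comp$orientation, 25, tolerance = 1)
})

test_that("fit_rf refuses maps without a genuine peak", {
  flat <- sensitivity_map(matrix(1, 21, 21), "sensitivity")
  expect_error(fit_rf(flat), "no-RF")
  raw <- sensitivity_map(matrix(1, 21, 21), "raw")
  expect_error(fit_rf(raw), "sensitivity-stage")
})

test_that("detect_coupling follows the peak/valley criteria", {
  # well-separated narrow lobes: coupled
  sep_cell <- two_rf_cell(sep = 8, w2 = 0.7, sigma = 1.5)
  sens <- scan_to_sens(sep_cell, smooth = FALSE)
  rf <- fit_rf(sens)
  cp <- detect_coupling(rf, sens)
  expect_true(cp$coupled)
  expect_true(any(cp$pairs$qualifies))
  expect_lt(min(cp$pairs$valley), 0.25)

  # same separation, wide lobes: one merged region, not coupled
  merged <- two_rf_cell(sep = 8, w2 = 0.7, sigma = 3)
  sens2 <- scan_to_sens(merged, smooth = FALSE)
  rf2 <- fit_rf(sens2)
  expect_false(detect_coupling(rf2, sens2)$coupled)

  # single-component model: no partner, never coupled
  single <- single_rf_cell(sigma = 2)
  sens3 <- scan_to_sens(single, smooth = FALSE)
  expect_false(detect_coupling(fit_rf(sens3), sens3)$coupled)
})

test_that("delay_difference recovers constructed latency offsets exactly", {
  proto <- grid_scan_protocol()
  cell <- two_rf_cell(sep = 8, w2 = 0.7, sigma = 1.5, lat2 = 3)
  tr <- simulate_grid_scan(cell, proto, seed = 1)
  sens <- scan_to_sens(cell, smooth = FALSE)
  rf <- fit_rf(sens)
  dd <- delay_difference(tr, proto, rf)
  # main latency 0, secondary +3 ms: t_max(main) - t_max(secondary) = -3
  expect_equal(dd$delta_t_ms[dd$role == "main"], 0)
  expect_equal(dd$delta_t_ms[dd$role == "coupled"], -3)

  same <- two_rf_cell(sep = 8, w2 = 0.7, sigma = 1.5, lat2 = 0)
  tr2 <- simulate_grid_scan(same, proto, seed = 2)
  rf2 <- fit_rf(scan_to_sens(same, smooth = FALSE))
  dd2 <- delay_difference(tr2, proto, rf2)
  expect_equal(dd2$delta_t_ms, c(0, 0))

  expect_error(delay_difference(tr, proto, fit_rf(scan_to_sens(
    single_rf_cell(), smooth = FALSE))), ">= 2 components")
})

test_that("average_fwhm averages high-quality recordings only", {
  mk_model <- function(fwhm, quality) {
    structure(list(components = data.frame(fwhm_circ = fwhm),
                   quality = quality), class = "rf_model")
  }
  expect_equal(average_fwhm(list(mk_model(6, "high"))), 6)
  expect_equal(average_fwhm(list(mk_model(6, "high"), mk_model(8, "high"))),
               7)
  expect_equal(average_fwhm(list(mk_model(6, "high"), mk_model(8, "high"),
                                 mk_model(99, "low"))), 7)
  expect_error(average_fwhm(list(mk_model(6, "low"))), "not estimable")
})
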