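test_that("spatial_profile matches the Gaussian closed form", {
  cell <- single_rf_cell(az = 1, el = -2, sigma = 2)
  expect_equal(spatial_profile(cell, 1, -2), 1.0)
  expect_equal(spatial_profile(cell, 3, -2), exp(-1 / 2), tolerance = 1e-12)
  # rotated elliptical component: 3 deg along the major axis at 30 deg
  cellr <- ground_truth_cell(data.frame(
    az = 0, el = 0, sigma_major = 3, sigma_minor = 1, orientation = 30,
    w = 1, latency_ms = 0), noise_sd_mV = 0)
  d <- 3 * c(cos(30 * pi / 180), sin(30 * pi / 180))
  expect_equal(spatial_profile(cellr, d[1], d[2]), exp(-1 / 2),
               tolerance = 1e-12)
})

test_that("two-component profile shows grid maxima with the weight ratio", {
  # oracle: evaluate the profile on the default grid, locate both local
  # maxima numerically and compare their values
  cell <- two_rf_cell(sep = 8, w2 = 0.5, sigma = 1.5)
  co <- grid_coordinates(grid_scan_protocol())
  vals <- outer(co$el_deg, co$az_deg,
                function(el, az) spatial_profile(cell, az, el))
  main_val <- vals[which(co$el_deg == 0), which(co$az_deg == -4)]
  sec_val <- vals[which(co$el_deg == 0), which(co$az_deg == 4)]
  expect_equal(main_val, max(vals))
  expect_lt(abs(sec_val / main_val - 0.5), 1e-6)
})

test_that("polarization_factor reproduces the cos^2-with-floor model", {
  flat <- single_rf_cell(); flat$ps_true <- 1
  expect_equal(polarization_factor(flat, seq(0, 179)), rep(1, 180))

  cell <- single_rf_cell(); cell$ps_true <- 10; cell$phi_max_true <- 40
  expect_equal(polarization_factor(cell, 40), 1)
  expect_equal(polarization_factor(cell, 130), 0.1, tolerance = 1e-12)

  # brute force over a sampled comb containing phi_max: max/min = PS exactly
  cell$ps_true <- 7.5; cell$phi_max_true <- 45
  f <- polarization_factor(cell, seq(0, 165, by = 15))
  expect_equal(max(f) / min(f), 7.5, tolerance = 1e-9)
})

test_that("spectral template peaks at lambda_max and is unimodal", {
  expect_equal(spectral_template(340, 340), 1.0)
  lam <- seq(300, 700, by = 1)
  tpl <- spectral_template(lam, 340)
  # the alpha band is flat near its peak: normalizing at lambda_max leaves
  # at most ~0.1% excess where the true template maximum sits
  expect_true(all(tpl > 0 & tpl <= 1 + 1e-3))
  peak <- which.max(tpl)
  expect_true(all(diff(tpl[seq_len(peak)]) > -1e-12))       # rising
  expect_true(all(diff(tpl[peak:length(tpl)]) < 1e-12))     # falling
  expect_error(spectral_template(250, 340), "range")
})

test_that("spectral template agrees with an independent transcription", {
  # independent oracle: the published A1 alpha-band closed form written out
  # again from scratch, peak-normalized the same way
  oracle <- function(lam, lmax) {
    A <- 69.7; B <- 28; C <- -14.9; D <- 0.674
    b <- 0.922; cc <- 1.104
    a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
    S <- function(l) {
      x <- lmax / l
      1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (cc - x)) + D)
    }
    S(lam) / S(lmax)
  }
  for (lmax in c(340, 350, 440)) {
    lam <- c(lmax - 40, lmax - 20, lmax + 20, lmax + 40)
    expect_equal(spectral_template(lam, lmax), oracle(lam, lmax),
                 tolerance = 1e-3)
  }
})

test_that("noiseless grid scan reproduces Hill(I0 * profile) epoch maxima", {
  cell <- single_rf_cell(az = 1, el = -2, sigma = 2)
  proto <- grid_scan_protocol()
  tr <- simulate_grid_scan(cell, proto, seed = 3)
  expect_equal(nrow(tr$markers), 441)    # conservation: one epoch per node
  ep <- epoch_amplitudes(tr, kinds = "flash", method = "maxmin")
  co <- grid_coordinates(proto)
  k <- ep$payload
  az <- co$az_deg[(k - 1) %% 21 + 1]
  el <- co$el_deg[(k - 1) %/% 21 + 1]
  want <- hill_response(3 * spatial_profile(cell, az, el), 40, 1, 1)
  expect_equal(ep$amplitude_mV, want, tolerance = 1e-9)
})

test_that("null cell and determinism contracts hold", {
  null_cell <- single_rf_cell()
  null_cell$components$w <- 1
  null_cell$v_max <- 1e-12               # effectively flat zero response
  tr <- simulate_grid_scan(null_cell, seed = 1)
  expect_lt(max(abs(tr$samples)), 1e-9)

  noisy <- single_rf_cell(noise_sd = 2)
  t1 <- simulate_grid_scan(noisy, seed = 42)
  t2 <- simulate_grid_scan(noisy, seed = 42)
  expect_identical(t1$samples, t2$samples)
  t3 <- simulate_grid_scan(noisy, seed = 43)
  expect_false(identical(t3$samples, t1$samples))
})

test_that("V-log(I) and polarizer series follow their forward models", {
  cell <- single_rf_cell()
  cell$ps_true <- 6; cell$phi_max_true <- 30
  ints <- 10^seq(-1.5, 1.5, length.out = 7)
  tr <- simulate_vlogi(cell, ints, seed = 1)
  ep <- epoch_amplitudes(tr, kinds = "intensity", method = "maxmin")
  expect_equal(ep$amplitude_mV,
               hill_response(ints, 40, 1, 1), tolerance = 1e-9)
  # intensity = K -> half-maximal response, by definition
  expect_equal(ep$amplitude_mV[ep$payload == 1], 20, tolerance = 1e-9)

  ser <- pol_series_exact(cell)
  want <- hill_response(3 * polarization_factor(cell, ser$angle_deg),
                        40, 1, 1)
  expect_equal(ser$response_mV, want, tolerance = 1e-9)

  unpol <- single_rf_cell(); unpol$ps_true <- 1
  ser2 <- pol_series_exact(unpol)
  expect_equal(diff(range(ser2$response_mV)), 0, tolerance = 1e-9)

  expect_error(simulate_vlogi(cell, c(1, 2, 3)), ">= 5")
  expect_error(simulate_pol_series(cell, c(0, 45, 90)), ">= 8")
})

test_that("ground-truth constructor enforces the main-cell invariant", {
  comp <- data.frame(az = 0, el = 0, sigma_major = 2, sigma_minor = 2,
                     orientation = 0, w = 0.8, latency_ms = 0)
  expect_error(ground_truth_cell(comp), "w = 1")
  comp2 <- rbind(comp, comp); comp2$w <- c(1, 1)
  expect_error(ground_truth_cell(comp2), "exactly one")
  comp$w <- 1; comp$sigma_minor <- -1
  expect_error(ground_truth_cell(comp), "sigmas")
})

test_that("population simulation is deterministic and honours the count table", {
  cfg <- simulation_config(seed = 11)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1, p2)
  expect_length(p1, sum(cfg$n_cells$n))
  regions <- vapply(p1, `[[`, "", "eye_region")
  expect_equal(sort(unique(regions)),
               sort(c("DRA", "main_retina", "marginal_DRA")))
})
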