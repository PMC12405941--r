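# shared fixtures: ground-truth cells and exact Hill fits for simulator
# round trips (no files; everything is generated in code)

FWHM_C <- 2 * sqrt(2 * log(2))          # sigma -> FWHM conversion constant

make_hill <- function(v_max = 40, k_half = 1, n = 1) {
  structure(list(v_max = v_max, k_half = k_half, n = n, rss = 0,
                 n_points = 9L), class = "hill_fit")
}

true_hill <- function(cell) make_hill(cell$v_max, cell$k_half, cell$n_hill)

single_rf_cell <- function(az = 0, el = 0, sigma = 2, noise_sd = 0, ...) {
  ground_truth_cell(
    data.frame(az = az, el = el, sigma_major = sigma, sigma_minor = sigma,
               orientation = 0, w = 1, latency_ms = 0),
    v_max = 40, k_half = 1, n_hill = 1, noise_sd_mV = noise_sd, ...)
}

two_rf_cell <- function(sep = 8, w2 = 0.7, sigma = 1.5, lat2 = 0,
                        noise_sd = 0, ...) {
  ground_truth_cell(
    data.frame(az = c(-sep / 2, sep / 2), el = c(0, 0),
               sigma_major = sigma, sigma_minor = sigma, orientation = 0,
               w = c(1, w2), latency_ms = c(0, lat2)),
    v_max = 40, k_half = 1, n_hill = 1, noise_sd_mV = noise_sd, ...)
}

# grid scan -> sensitivity map, optionally skipping the smoothing stage
# (noiseless fixtures need the analytic, unblurred map)
scan_to_sens <- function(cell, seed = 1, smooth = TRUE,
                         proto = grid_scan_protocol(), hill = NULL) {
  if (is.null(hill)) hill <- true_hill(cell)
  tr <- simulate_grid_scan(cell, proto, seed = seed)
  m <- extract_raw_map(tr, proto)
  if (smooth) m <- smooth_map(m)
  to_sensitivity(m, hill)
}

# polarizer series with exact (max - min) amplitudes, for noise-off checks
pol_series_exact <- function(cell, angles = seq(0, 165, by = 15), seed = 1) {
  tr <- simulate_pol_series(cell, angles, seed = seed)
  ep <- epoch_amplitudes(tr, kinds = "polarizer", method = "maxmin")
  data.frame(angle_deg = ep$payload, response_mV = ep$amplitude_mV)
}
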