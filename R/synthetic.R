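#' Ground-truth synthetic cell
#'
#' Defines a simulated photoreceptor with full ground truth: one or more
#' receptive-field components (the main cell plus optional coupled
#' secondaries), a Hill intensity-response nonlinearity, cos^2-type
#' polarization tuning, a UV spectral peak and additive recording noise.
#' Every downstream estimator in the package can be validated by parameter
#' recovery against these fields.
#'
#' @param components Data frame with one row per RF component and columns
#'   `az`, `el` (centre, deg), `sigma_major`, `sigma_minor` (deg, > 0),
#'   `orientation` (deg), `w` (relative amplitude in (0, 1]; exactly one
#'   component — the main cell — must have `w = 1`), `latency_ms`
#'   (response latency offset, ms).
#' @param v_max Hill maximum response (mV).
#' @param k_half Hill half-maximum intensity (relative intensity units).
#' @param n_hill Hill slope.
#' @param ps_true Polarization sensitivity (>= 1).
#' @param phi_max_true Preferred e-vector angle (deg, taken mod 180).
#' @param lambda_max Spectral peak (nm), default 340 (UV receptor).
#' @param noise_sd_mV Additive Gaussian noise sd; default 5% of `v_max`.
#' @param species,eye_region Metadata carried through the pipeline.
#' @param time_to_peak_ms Time to peak of the flash-response kernel (ms).
#' @return An object of class `ground_truth_cell`.
#' @export
ground_truth_cell <- function(components, v_max = 40, k_half = 1, n_hill = 1,
                              ps_true = 6, phi_max_true = 90,
                              lambda_max = 340,
                              noise_sd_mV = 0.05 * v_max,
                              species = "Apis", eye_region = "DRA",
                              time_to_peak_ms = 30) {
  components <- as.data.frame(components)
  need <- c("az", "el", "sigma_major", "sigma_minor", "orientation", "w",
            "latency_ms")
  miss <- setdiff(need, names(components))
  if ("latency_ms" %in% miss) components$latency_ms <- 0
  if ("orientation" %in% miss) components$orientation <- 0
  miss <- setdiff(need, names(components))
  if (length(miss)) stop("components missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(components$sigma_major <= 0) || any(components$sigma_minor <= 0)) {
    stop("all sigmas must be > 0", call. = FALSE)
  }
  if (any(components$w <= 0) || any(components$w > 1)) {
    stop("component weights must lie in (0, 1]", call. = FALSE)
  }
  if (sum(abs(components$w - 1) < 1e-12) != 1L) {
    stop("exactly one component (the main cell) must have w = 1",
         call. = FALSE)
  }
  if (ps_true < 1) stop("ps_true must be >= 1", call. = FALSE)
  stopifnot(v_max > 0, k_half > 0, n_hill > 0, noise_sd_mV >= 0)
  structure(
    list(components = components, v_max = v_max, k_half = k_half,
         n_hill = n_hill, ps_true = ps_true,
         phi_max_true = phi_max_true %% 180, lambda_max = lambda_max,
         noise_sd_mV = noise_sd_mV, species = species,
         eye_region = eye_region, time_to_peak_ms = time_to_peak_ms),
    class = "ground_truth_cell"
  )
}

#' Forward spatial sensitivity profile of a ground-truth cell
#'
#' Sum over RF components of `w_k * exp(-q_k/2)` where `q_k` is the rotated
#' anisotropic quadratic form of component k, clipped at 1. This is the same
#' elliptical-Gaussian family the fitting stage uses, so noise-free recovery
#' is exact.
#'
#' @param cell A [ground_truth_cell()].
#' @param az,el Azimuth / elevation (deg); vectors are recycled to a common
#'   length.
#' @return Relative sensitivity in \[0, 1\].
#' @export
spatial_profile <- function(cell, az, el) {
  co <- cell$components
  out <- 0
  for (k in seq_len(nrow(co))) {
    th <- co$orientation[k] * pi / 180
    dx <- az - co$az[k]; dy <- el - co$el[k]
    u <- cos(th) * dx + sin(th) * dy
    v <- -sin(th) * dx + cos(th) * dy
    q <- (u / co$sigma_major[k])^2 + (v / co$sigma_minor[k])^2
    out <- out + co$w[k] * exp(-q / 2)
  }
  pmin(out, 1)
}

#' Polarization (Malus-type) modulation factor
#'
#' The cos^2 tuning model with floor `1/PS`:
#' `f(phi) = 1/PS + (1 - 1/PS) * cos^2(phi - phi_max)`, so that
#' `f(phi_max) = 1`, `min f = 1/PS`, and the max/min sensitivity ratio over
#' e-vector angle equals the cell's true PS exactly.
#'
#' @param cell A [ground_truth_cell()].
#' @param phi_deg E-vector angle(s) in degrees.
#' @return Multiplicative sensitivity factor in (0, 1].
#' @export
polarization_factor <- function(cell, phi_deg) {
  ps <- cell$ps_true
  d <- (phi_deg - cell$phi_max_true) * pi / 180
  1 / ps + (1 - 1 / ps) * cos(d)^2
}

#' A1 visual-pigment absorbance template
#'
#' Relative spectral sensitivity of a rhodopsin (A1 chromophore) alpha band
#' as a function of wavelength, parameterized only by the peak wavelength
#' `lambda_max`. Uses the standard published closed form (sum of three
#' exponentials plus a constant in `x = lambda_max / lambda`), renormalized
#' so the value at `lambda_max` is exactly 1.
#'
#' @param lambda_nm Wavelength(s), nm; must lie in \[300, 700\].
#' @param lambda_max Peak wavelength, nm.
#' @return Relative sensitivity in (0, 1].
#' @export
spectral_template <- function(lambda_nm, lambda_max) {
  if (any(lambda_nm < 300 | lambda_nm > 700)) {
    stop("wavelength outside supported range [300, 700] nm", call. = FALSE)
  }
  a1 <- function(lam, lmax) {
    x <- lmax / lam
    a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
    1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
           exp(-14.9 * (1.104 - x)) + 0.674)
  }
  a1(lambda_nm, lambda_max) / a1(lambda_max, lambda_max)
}

#' Hill (Naka-Rushton) intensity-response function
#'
#' `V(I) = v_max * I^n / (I^n + k^n)`.
#'
#' @param intensity Relative intensity (>= 0).
#' @param v_max Maximum response (mV).
#' @param k_half Half-maximum intensity.
#' @param n_hill Hill slope.
#' @return Response in mV.
#' @export
hill_response <- function(intensity, v_max, k_half, n_hill) {
  ii <- pmax(intensity, 0)^n_hill
  v_max * ii / (ii + k_half^n_hill)
}

# Gamma-shaped flash-response kernel (shape 3), peak value 1 at
# `time_to_peak_ms`; length covers one stimulus epoch.
response_kernel <- function(sampling_rate, time_to_peak_ms = 30,
                            duration_ms = 120) {
  dt_ms <- 1000 / sampling_rate
  t <- seq(0, duration_ms, by = dt_ms)
  # shape-3 gamma, normalized so g(time_to_peak) = 1:
  # g(t) = (t/tp)^2 * exp(2 * (1 - t/tp)), mode at t = tp
  (t / time_to_peak_ms)^2 * exp(2 * (1 - t / time_to_peak_ms))
}

# Place amplitude-scaled, latency-shifted kernels at each epoch onset.
build_epoch_trace <- function(amplitudes, latencies_ms, onsets_s,
                              total_s, sampling_rate, time_to_peak_ms,
                              noise_sd, kernel_duration_ms = 120) {
  n <- round(total_s * sampling_rate)
  samples <- numeric(n)
  kern <- response_kernel(sampling_rate, time_to_peak_ms, kernel_duration_ms)
  for (k in seq_along(amplitudes)) {
    if (amplitudes[k] == 0) next
    i0 <- round((onsets_s[k] + latencies_ms[k] / 1000) * sampling_rate) + 1L
    idx <- i0:min(i0 + length(kern) - 1L, n)
    samples[idx] <- samples[idx] + amplitudes[k] * kern[seq_along(idx)]
  }
  if (noise_sd > 0) samples <- samples + stats::rnorm(n, 0, noise_sd)
  samples
}

#' Simulate a grid-scan recording
#'
#' Produces the voltage trace of the receptive-field mapping protocol: one
#' flash epoch per grid node in row-major scan order. The depolarization
#' amplitude at node p is `Hill(I0 * spatial_profile(p))`; the waveform is a
#' gamma-shaped kernel delayed by the latency of whichever RF component
#' dominates that node; Gaussian noise with sd `cell$noise_sd_mV` is added.
#' Markers record every flash onset with the 1-based position index as
#' payload.
#'
#' @param cell A [ground_truth_cell()].
#' @param protocol A [grid_scan_protocol()].
#' @param seed Integer seed (determinism contract: same seed, same trace).
#' @param i0 Flash intensity in Hill units at full sensitivity; default
#'   `3 * k_half` (bright but sub-saturating).
#' @param sampling_rate Hz, default 1000.
#' @return A [recording_trace()].
#' @export
simulate_grid_scan <- function(cell, protocol = grid_scan_protocol(),
                               seed = 1L, i0 = 3 * cell$k_half,
                               sampling_rate = 1000) {
  set.seed(seed)
  coords <- grid_coordinates(protocol)
  pos <- expand.grid(col = seq_len(protocol$n_cols),
                     row = seq_len(protocol$n_rows))[, c("row", "col")]
  # row-major: all columns of row 1 first
  pos <- pos[order(pos$row, pos$col), ]
  az <- coords$az_deg[pos$col]
  el <- coords$el_deg[pos$row]
  prof <- spatial_profile(cell, az, el)
  amp <- hill_response(i0 * prof, cell$v_max, cell$k_half, cell$n_hill)
  lat <- dominant_latency(cell, az, el)
  n_ep <- nrow(pos)
  period_s <- protocol$period_ms / 1000
  onsets <- (seq_len(n_ep) - 1L) * period_s
  samples <- build_epoch_trace(amp, lat, onsets, n_ep * period_s,
                               sampling_rate, cell$time_to_peak_ms,
                               cell$noise_sd_mV)
  markers <- data.frame(time_s = onsets, kind = "flash",
                        payload = seq_len(n_ep))
  recording_trace(samples, sampling_rate, 0, markers)
}

# Latency of the component contributing most at each point (excluding the
# constant clip); vectorized over positions.
dominant_latency <- function(cell, az, el) {
  co <- cell$components
  best <- rep(1L, length(az))
  best_val <- rep(-Inf, length(az))
  for (k in seq_len(nrow(co))) {
    th <- co$orientation[k] * pi / 180
    dx <- az - co$az[k]; dy <- el - co$el[k]
    u <- cos(th) * dx + sin(th) * dy
    v <- -sin(th) * dx + cos(th) * dy
    q <- (u / co$sigma_major[k])^2 + (v / co$sigma_minor[k])^2
    val <- co$w[k] * exp(-q / 2)
    sel <- val > best_val
    best[sel] <- k
    best_val[sel] <- val[sel]
  }
  co$latency_ms[best]
}

#' Simulate a V-log(I) intensity series
#'
#' One flash per intensity step; the peak amplitude of each response follows
#' the cell's Hill function. Markers carry the relative intensity.
#'
#' @param cell A [ground_truth_cell()].
#' @param intensities Relative intensities (>= 5 steps).
#' @param seed Integer seed.
#' @param period_ms Epoch length per step.
#' @param sampling_rate Hz.
#' @return A [recording_trace()].
#' @export
simulate_vlogi <- function(cell, intensities, seed = 1L, period_ms = 200,
                           sampling_rate = 1000) {
  if (length(intensities) < 5L) stop("need >= 5 intensity steps",
                                     call. = FALSE)
  set.seed(seed)
  amp <- hill_response(intensities, cell$v_max, cell$k_half, cell$n_hill)
  onsets <- (seq_along(intensities) - 1L) * period_ms / 1000
  samples <- build_epoch_trace(amp, rep(0, length(amp)), onsets,
                               length(amp) * period_ms / 1000,
                               sampling_rate, cell$time_to_peak_ms,
                               cell$noise_sd_mV)
  markers <- data.frame(time_s = onsets, kind = "intensity",
                        payload = as.numeric(intensities))
  recording_trace(samples, sampling_rate, 0, markers)
}

#' Simulate a polarizer-angle series
#'
#' One flash per polarizer angle at fixed intensity; peak amplitudes follow
#' `Hill(I0 * polarization_factor(phi))`. Markers carry the angle (deg).
#'
#' @param cell A [ground_truth_cell()].
#' @param angles_deg E-vector angles (>= 8, spanning >= 180 deg recommended).
#' @param seed Integer seed.
#' @param i0 Flash intensity in Hill units, default `3 * k_half`.
#' @param period_ms Epoch length per angle.
#' @param sampling_rate Hz.
#' @return A [recording_trace()].
#' @export
simulate_pol_series <- function(cell, angles_deg, seed = 1L,
                                i0 = 3 * cell$k_half, period_ms = 200,
                                sampling_rate = 1000) {
  if (length(angles_deg) < 8L) stop("need >= 8 polarizer angles",
                                    call. = FALSE)
  set.seed(seed)
  f <- polarization_factor(cell, angles_deg)
  amp <- hill_response(i0 * f, cell$v_max, cell$k_half, cell$n_hill)
  onsets <- (seq_along(angles_deg) - 1L) * period_ms / 1000
  samples <- build_epoch_trace(amp, rep(0, length(amp)), onsets,
                               length(amp) * period_ms / 1000,
                               sampling_rate, cell$time_to_peak_ms,
                               cell$noise_sd_mV)
  markers <- data.frame(time_s = onsets, kind = "polarizer",
                        payload = as.numeric(angles_deg))
  recording_trace(samples, sampling_rate, 0, markers)
}

#' Draw a random ground-truth cell for one eye region
#'
#' Region-typical parameter ranges emulate the contrast between eye
#' regions: main-retina cells are small-field, weakly polarization
#' sensitive and ~10x more light-sensitive (lower `k_half`) than DRA cells;
#' DRA cells are wide-field, strongly polarization-sensitive, with steeper
#' Hill slopes and a chance of coupled secondary RFs.
#'
#' @param species `"Apis"` or `"Bombus"`.
#' @param eye_region `"main_retina"`, `"marginal_DRA"` or `"DRA"`.
#' @param coupling_prob Probability that a DRA-type cell carries a coupled
#'   secondary component (default 0.25, the observed fraction of coupled
#'   DRA recordings).
#' @param noise_frac Noise sd as a fraction of `v_max` (default 0.05).
#' @return A [ground_truth_cell()]. Uses the current RNG state; seed it
#'   with `set.seed()` (or via [simulate_population()]).
#' @export
random_cell <- function(species = c("Apis", "Bombus"),
                        eye_region = c("DRA", "marginal_DRA", "main_retina"),
                        coupling_prob = 0.25, noise_frac = 0.05) {
  species <- match.arg(species)
  eye_region <- match.arg(eye_region)
  rng <- switch(eye_region,
    main_retina = list(fwhm = c(2, 4), ps = c(1.2, 3), k = c(0.08, 0.15),
                       n = c(0.6, 1.0), couple = 0),
    marginal_DRA = list(fwhm = c(4, 6.5), ps = c(4, 9), k = c(0.08, 0.2),
                        n = c(0.8, 1.1), couple = 0),
    DRA = list(fwhm = c(5, 9), ps = c(4, 12), k = c(0.8, 1.5),
               n = c(0.9, 1.2), couple = coupling_prob))
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  fwhm <- runif1(rng$fwhm)
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  ecc <- stats::runif(1, 1, 1.4)        # mild ellipticity
  comp <- data.frame(
    az = stats::runif(1, -2, 2), el = stats::runif(1, -2, 2),
    sigma_major = sig * sqrt(ecc), sigma_minor = sig / sqrt(ecc),
    orientation = stats::runif(1, 0, 180), w = 1, latency_ms = 0)
  if (stats::runif(1) < rng$couple) {
    # Coupled secondaries come from neighbouring rhabdoms: both lobes are
    # individual-rhabdom-scale fields whose centres sit 6-9 deg apart and
    # whose widths are small enough relative to that separation
    # (FWHM <= 0.45 * separation) that the two high-sensitivity regions are
    # split by a valley below ~20% of maximum — the coupling signature.
    # The secondary is clearly supra-threshold (w > 0.5, above the
    # half-maximum coupling criterion) with a 0-5 ms latency lag.
    sep <- stats::runif(1, 6, 9)
    sig_c <- stats::runif(1, 2.5, 0.45 * sep) / (2 * sqrt(2 * log(2)))
    comp$sigma_major <- comp$sigma_minor <- sig_c
    repeat {
      ang <- stats::runif(1, 0, 2 * pi)
      az2 <- comp$az[1] + sep * cos(ang)
      el2 <- comp$el[1] + sep * sin(ang)
      if (abs(az2) <= 8 && abs(el2) <= 8) break
    }
    comp <- rbind(comp, data.frame(
      az = az2, el = el2,
      sigma_major = sig_c, sigma_minor = sig_c,
      orientation = comp$orientation[1],
      w = stats::runif(1, 0.55, 0.9),
      latency_ms = stats::runif(1, 0, 5)))
  }
  v_max <- stats::runif(1, 30, 50)
  ground_truth_cell(
    comp, v_max = v_max, k_half = runif1(rng$k), n_hill = runif1(rng$n),
    ps_true = runif1(rng$ps), phi_max_true = stats::runif(1, 0, 180),
    lambda_max = 340, noise_sd_mV = noise_frac * v_max,
    species = species, eye_region = eye_region)
}

#' Simulation configuration
#'
#' @param seed Integer master seed; identical seed and configuration give
#'   bit-identical simulated populations.
#' @param n_cells Named-count data frame with columns `species`,
#'   `eye_region`, `n`; default a 12-cell demo population (two per species
#'   x region).
#' @param coupling_prob,noise_frac Passed to [random_cell()].
#' @param protocol A [grid_scan_protocol()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_cells = NULL,
                              coupling_prob = 0.25, noise_frac = 0.05,
                              protocol = grid_scan_protocol()) {
  if (is.null(n_cells)) {
    n_cells <- expand.grid(species = c("Apis", "Bombus"),
                           eye_region = c("main_retina", "marginal_DRA", "DRA"),
                           stringsAsFactors = FALSE)
    n_cells$n <- 2L
  }
  stopifnot(all(c("species", "eye_region", "n") %in% names(n_cells)))
  structure(list(seed = as.integer(seed), n_cells = n_cells,
                 coupling_prob = coupling_prob, noise_frac = noise_frac,
                 protocol = protocol),
            class = "simulation_config")
}

#' Simulate a ground-truth cell population
#'
#' @param config A [simulation_config()].
#' @return Named list of [ground_truth_cell()] objects (`cell_001`, ...),
#'   each with a `$sim_seed` attribute used for its trace simulations.
#' @export
simulate_population <- function(config) {
  set.seed(config$seed)
  cells <- list()
  idx <- 0L
  for (i in seq_len(nrow(config$n_cells))) {
    row <- config$n_cells[i, ]
    for (j in seq_len(row$n)) {
      idx <- idx + 1L
      cell <- random_cell(row$species, row$eye_region,
                          coupling_prob = config$coupling_prob,
                          noise_frac = config$noise_frac)
      cell$cell_id <- sprintf("cell_%03d", idx)
      cell$sim_seed <- (config$seed %% 1000000L) * 1000L + idx
      cells[[cell$cell_id]] <- cell
    }
  }
  cells
}
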