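#' Extract the raw spatial-sensitivity map from a grid-scan trace
#'
#' Each row of the scan is divided into `n_cols` equal parts (one 145 ms
#' epoch per grid node); the raw map value at (row, col) is the maximum
#' voltage of that epoch minus its minimum, which removes the per-epoch
#' baseline (roughly the background noise floor) and is therefore
#' nonnegative by construction.
#'
#' @param trace A [recording_trace()] with flash markers whose payload is
#'   the 1-based row-major position index.
#' @param protocol The [grid_scan_protocol()] used.
#' @return A [sensitivity_map()] with `stage = "raw"`.
#' @export
extract_raw_map <- function(trace, protocol = grid_scan_protocol()) {
  mk <- trace$markers[trace$markers$kind == "flash", ]
  n_expect <- protocol$n_rows * protocol$n_cols
  present <- sort(unique(mk$payload))
  missing <- setdiff(seq_len(n_expect), present)
  if (length(missing)) {
    stop("missing epochs for positions: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) " ...", call. = FALSE)
  }
  period_n <- round(protocol$period_ms / 1000 * trace$sampling_rate)
  vals <- matrix(NA_real_, protocol$n_rows, protocol$n_cols)
  for (i in seq_len(nrow(mk))) {
    k <- mk$payload[i]
    i0 <- round((mk$time_s[i] - trace$t0) * trace$sampling_rate) + 1L
    seg <- trace$samples[i0:min(i0 + period_n - 1L, length(trace$samples))]
    r <- ((k - 1L) %/% protocol$n_cols) + 1L
    c <- ((k - 1L) %% protocol$n_cols) + 1L
    vals[r, c] <- max(seg) - min(seg)
  }
  coords <- grid_coordinates(protocol)
  sensitivity_map(vals, "raw", az_deg = coords$az_deg, el_deg = coords$el_deg)
}

# 1-D Gaussian kernel sampled at integer pixel offsets, radius
# floor(truncate*sigma + 0.5), normalized to sum 1 (matches the common
# ndimage discretization).
gauss_kernel_1d <- function(sigma_px, truncate = 4) {
  radius <- max(as.integer(truncate * sigma_px + 0.5), 0L)
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Reflect-mode 1-D convolution along rows of a matrix (edge sample
# duplicated: d c b a | a b c d | d c b a), valid for any kernel radius.
conv_rows_reflect <- function(m, kern) {
  radius <- (length(kern) - 1L) %/% 2L
  if (radius == 0L) return(m)
  n <- ncol(m)
  pos <- (1L - radius):(n + radius)
  q <- (pos - 1L) %% (2L * n)
  ref <- ifelse(q < n, q + 1L, 2L * n - q)
  padded <- m[, ref, drop = FALSE]
  out <- matrix(0, nrow(m), n)
  for (j in seq_along(kern)) {
    out <- out + kern[j] * padded[, j:(j + n - 1L), drop = FALSE]
  }
  out
}

#' Gaussian-smooth a raw sensitivity map
#'
#' Separable 2-D Gaussian filtering of the raw voltage map (default sd
#' 1 deg) with a reflect boundary, preserving nonnegativity and the DC
#' level (the kernel is normalized).
#'
#' @param map A [sensitivity_map()] with `stage = "raw"`.
#' @param sigma_deg Kernel standard deviation in degrees (> 0).
#' @param step_deg Grid step used to convert sigma to pixels; defaults to
#'   the azimuth spacing stored in the map.
#' @return A [sensitivity_map()] with `stage = "smoothed"`.
#' @export
smooth_map <- function(map, sigma_deg = 1, step_deg = NULL) {
  stopifnot(inherits(map, "sensitivity_map"))
  if (map$stage != "raw") stop("smooth_map expects a raw-stage map",
                               call. = FALSE)
  if (!is.numeric(sigma_deg) || sigma_deg <= 0) {
    stop("sigma_deg must be > 0", call. = FALSE)
  }
  if (is.null(step_deg)) {
    step_deg <- if (length(map$az_deg) > 1L) diff(map$az_deg)[1L] else 1
  }
  kern <- gauss_kernel_1d(sigma_deg / step_deg)
  v <- conv_rows_reflect(map$values, kern)
  v <- t(conv_rows_reflect(t(v), kern))
  v[v < 0] <- 0
  sensitivity_map(v, "smoothed", az_deg = map$az_deg, el_deg = map$el_deg)
}

#' Transform a voltage map to a relative-sensitivity map
#'
#' Subtracts the map's background pedestal (the `bg_quantile` quantile of
#' the map values, clamped at zero), divides by the cell's fitted `v_max`,
#' applies the inverse Hill transformation elementwise, then rescales so
#' the map maximum equals 1.
#'
#' The pedestal subtraction matters because the per-epoch `max - min`
#' extraction adds the expected range of the recording noise (several noise
#' sd) uniformly to every grid node; without removing it, that offset is
#' amplified by the convex inverse Hill transformation and can push the
#' peak into the clipping region. On a noiseless map the background
#' quantile is zero and the transformation is exact.
#'
#' @param map A [sensitivity_map()] (stage `"smoothed"`, or `"raw"` when
#'   smoothing is deliberately skipped).
#' @param hill The cell's `hill_fit` (supplies `v_max` and the slope `n`).
#' @param r_cap Clipping ceiling passed to [inverse_hill()].
#' @param bg_quantile Quantile of map values used as the background
#'   pedestal estimate; the default 0 takes the map minimum (the quietest
#'   grid node defines zero response, echoing the per-epoch
#'   minimum-subtraction idea). `NULL` disables subtraction.
#' @return A [sensitivity_map()] with `stage = "sensitivity"`, max = 1,
#'   carrying attribute `clipped`.
#' @export
to_sensitivity <- function(map, hill, r_cap = 0.99, bg_quantile = 0) {
  stopifnot(inherits(map, "sensitivity_map"), inherits(hill, "hill_fit"))
  if (max(map$values) <= 0) stop("degenerate map: all-zero", call. = FALSE)
  bg <- if (is.null(bg_quantile)) 0 else
    stats::quantile(map$values, bg_quantile, names = FALSE)
  r <- pmax(map$values - bg, 0) / hill$v_max
  s <- inverse_hill(r, hill, r_cap = r_cap)
  clipped <- attr(s, "clipped")
  v <- matrix(as.numeric(s), nrow(map$values), ncol(map$values))
  v <- v / max(v)
  out <- sensitivity_map(v, "sensitivity", az_deg = map$az_deg,
                         el_deg = map$el_deg)
  attr(out, "clipped") <- clipped
  out
}

# ---- elliptical Gaussian mixture fit ---------------------------------------

gauss2d_component <- function(az, el, p) {
  # p = c(A, cx, cy, s_major, s_minor, theta_rad)
  dx <- az - p[2]; dy <- el - p[3]
  u <- cos(p[6]) * dx + sin(p[6]) * dy
  v <- -sin(p[6]) * dx + cos(p[6]) * dy
  p[1] * exp(-((u / p[4])^2 + (v / p[5])^2) / 2)
}

rf_predict_raw <- function(par, k, az, el) {
  pred <- rep(par[1L], length(az))      # offset first
  for (j in seq_len(k)) {
    pj <- par[(2L + (j - 1L) * 6L):(1L + j * 6L)]
    pred <- pred + gauss2d_component(az, el, pj)
  }
  pred
}

# local maxima of a matrix (8-neighbourhood, strict on at least one side),
# returned in decreasing order of value
local_maxima <- function(values) {
  nr <- nrow(values); nc <- ncol(values)
  padded <- matrix(-Inf, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- values
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- padded[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
    is_max <- is_max & (values >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  ord <- order(values[idx], decreasing = TRUE)
  idx[ord, , drop = FALSE]
}

# non-maximum suppression: drop maxima within `radius` deg of a stronger one
nms_peaks <- function(peaks_az, peaks_el, radius = 2) {
  keep <- logical(length(peaks_az))
  for (i in seq_along(peaks_az)) {
    ok <- TRUE
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if ((peaks_az[i] - peaks_az[j])^2 + (peaks_el[i] - peaks_el[j])^2 <
          radius^2) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  keep
}

fwhm_from_sigma <- function(sigma) 2 * sqrt(2 * log(2)) * sigma

#' Fit a weighted elliptical-Gaussian receptive-field model
#'
#' Models the sensitivity map as a constant offset plus 1 to
#' `max_components` elliptical Gaussian components, fitted by bounded least
#' squares. Fits are initialized from the strongest local maxima of the map
#' after non-maximum suppression (radius 2 deg); the number of components
#' is selected by BIC. The largest-amplitude component is designated the
#' main cell (`weight = 1`); all others are potential coupled secondaries
#' with `weight = amplitude / max amplitude`. Each component carries its
#' axis FWHMs and the equal-area circular FWHM
#' `fwhm_circ = sqrt(fwhm_major * fwhm_minor)`.
#'
#' @param map A [sensitivity_map()] with `stage = "sensitivity"`.
#' @param max_components Maximum number of Gaussian components (1-3).
#' @param sigma_bounds Allowed sigma range in degrees.
#' @param quality_peak_ratio A fit is `quality = "high"` when the map peak
#'   is at least this multiple of the background median (default 5).
#' @return An object of class `rf_model`: `components` (data frame sorted
#'   by weight, columns `role, amplitude, weight, center_az, center_el,
#'   sigma_major, sigma_minor, orientation, fwhm_major, fwhm_minor,
#'   fwhm_circ`), `offset`, `rss`, `n_components`, `bic` (per candidate k),
#'   `quality`.
#' @export
fit_rf <- function(map, max_components = 3, sigma_bounds = c(0.3, 15),
                   quality_peak_ratio = 5) {
  stopifnot(inherits(map, "sensitivity_map"))
  if (map$stage != "sensitivity") {
    stop("fit_rf expects a sensitivity-stage map", call. = FALSE)
  }
  values <- map$values
  bg <- stats::median(values)
  # values is rows=el, cols=az; flatten row-major so az varies fastest
  az <- rep(map$az_deg, times = length(map$el_deg))
  el <- rep(map$el_deg, each = length(map$az_deg))
  y <- as.numeric(t(values))
  pk <- local_maxima(values)
  pk_val <- values[pk]
  sel <- pk_val > max(3 * bg, 1e-3)
  pk <- pk[sel, , drop = FALSE]; pk_val <- pk_val[sel]
  if (nrow(pk) == 0L) stop("no-RF error: no local maximum above 3x background",
                           call. = FALSE)
  pk_az <- map$az_deg[pk[, 2L]]
  pk_el <- map$el_deg[pk[, 1L]]
  keep <- nms_peaks(pk_az, pk_el, radius = 2)
  pk_az <- pk_az[keep]; pk_el <- pk_el[keep]; pk_val <- pk_val[keep]
  az_rng <- range(map$az_deg); el_rng <- range(map$el_deg)
  n_obs <- length(y)
  fits <- list(); bics <- rep(NA_real_, max_components)
  for (k in seq_len(min(max_components, length(pk_az)))) {
    par0 <- c(min(bg, 0.4))
    lo <- 0; hi <- 0.8
    for (j in seq_len(k)) {
      par0 <- c(par0, max(pk_val[j] - bg, 0.05), pk_az[j], pk_el[j], 2, 2, 0)
      lo <- c(lo, 1e-3, az_rng[1] - 2, el_rng[1] - 2,
              sigma_bounds[1], sigma_bounds[1], -pi)
      hi <- c(hi, 1.5, az_rng[2] + 2, el_rng[2] + 2,
              sigma_bounds[2], sigma_bounds[2], 2 * pi)
    }
    obj <- function(p) sum((rf_predict_raw(p, k, az, el) - y)^2)
    fit <- stats::optim(par0, obj, method = "L-BFGS-B", lower = lo,
                        upper = hi,
                        control = list(maxit = 400, factr = 1e4))
    rss <- fit$value
    p_free <- length(par0)
    bics[k] <- n_obs * log(max(rss, n_obs * 1e-14) / n_obs) +
      p_free * log(n_obs)
    fits[[k]] <- list(par = fit$par, rss = rss, k = k)
  }
  k_best <- which.min(bics)
  best <- fits[[k_best]]
  comp <- do.call(rbind, lapply(seq_len(best$k), function(j) {
    pj <- best$par[(2L + (j - 1L) * 6L):(1L + j * 6L)]
    s1 <- pj[4]; s2 <- pj[5]; th <- pj[6] * 180 / pi
    if (s2 > s1) { tmp <- s1; s1 <- s2; s2 <- tmp; th <- th + 90 }
    data.frame(amplitude = pj[1], center_az = pj[2], center_el = pj[3],
               sigma_major = s1, sigma_minor = s2,
               orientation = th %% 180)
  }))
  comp <- comp[order(comp$amplitude, decreasing = TRUE), , drop = FALSE]
  comp$weight <- comp$amplitude / comp$amplitude[1L]
  comp$role <- c("main", rep("coupled", nrow(comp) - 1L))
  comp$fwhm_major <- fwhm_from_sigma(comp$sigma_major)
  comp$fwhm_minor <- fwhm_from_sigma(comp$sigma_minor)
  comp$fwhm_circ <- sqrt(comp$fwhm_major * comp$fwhm_minor)
  rownames(comp) <- NULL
  quality <- if (max(values) >= quality_peak_ratio * max(bg, 1e-12))
    "high" else "low"
  structure(
    list(components = comp[, c("role", "amplitude", "weight", "center_az",
                               "center_el", "sigma_major", "sigma_minor",
                               "orientation", "fwhm_major", "fwhm_minor",
                               "fwhm_circ")],
         offset = best$par[1L], rss = best$rss, n_components = best$k,
         bic = bics, quality = quality, map_stage = map$stage),
    class = "rf_model"
  )
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d component(s), offset=%.3f, rss=%.3g, quality=%s\n",
              x$n_components, x$offset, x$rss, x$quality))
  print(x$components, digits = 4)
  invisible(x)
}

#' Predict model sensitivity at arbitrary positions
#'
#' @param object An `rf_model`.
#' @param az,el Positions in degrees.
#' @param ... Unused.
#' @return Predicted relative sensitivity.
#' @export
predict.rf_model <- function(object, az, el, ...) {
  co <- object$components
  pred <- rep(object$offset, length(az))
  for (j in seq_len(nrow(co))) {
    pred <- pred + gauss2d_component(
      az, el, c(co$amplitude[j], co$center_az[j], co$center_el[j],
                co$sigma_major[j], co$sigma_minor[j],
                co$orientation[j] * pi / 180))
  }
  pred
}

# bilinear interpolation of a sensitivity map at (az, el); clamped to grid
map_interp <- function(map, az, el) {
  ax <- map$az_deg
  ey <- map$el_deg                      # decreasing
  fx <- (az - ax[1]) / (ax[2] - ax[1]) + 1
  fy <- (el - ey[1]) / (ey[2] - ey[1]) + 1
  fx <- pmin(pmax(fx, 1), length(ax))
  fy <- pmin(pmax(fy, 1), length(ey))
  x0 <- pmin(floor(fx), length(ax) - 1L); y0 <- pmin(floor(fy), length(ey) - 1L)
  wx <- fx - x0; wy <- fy - y0
  v <- map$values
  v[cbind(y0, x0)] * (1 - wx) * (1 - wy) +
    v[cbind(y0, x0 + 1L)] * wx * (1 - wy) +
    v[cbind(y0 + 1L, x0)] * (1 - wx) * wy +
    v[cbind(y0 + 1L, x0 + 1L)] * wx * wy
}

#' Detect photoreceptor coupling in a fitted RF model
#'
#' A cell is flagged as coupled when at least two model components each
#' reach more than `peak_threshold` (default 0.5) of the map maximum at
#' their centres, and the sensitivity map along the straight line between
#' those centres drops below `valley_threshold` (default 0.25) of the map
#' maximum — i.e. multiple high-sensitivity regions separated by a
#' low-sensitivity gap, the signature of spatial summation across
#' neighbouring ommatidia rather than a single elongated RF.
#'
#' @param model An `rf_model`.
#' @param map The `sensitivity`-stage [sensitivity_map()] the model was
#'   fitted to.
#' @param peak_threshold Fraction of map maximum a component centre must
#'   reach.
#' @param valley_threshold Fraction of map maximum below which the
#'   inter-peak valley must fall.
#' @return List: `coupled` (logical), `pairs` (data frame of qualifying
#'   component pairs with their valley minima), `profiles` (list of
#'   along-line sensitivity profiles for diagnostics).
#' @export
detect_coupling <- function(model, map, peak_threshold = 0.5,
                            valley_threshold = 0.25) {
  stopifnot(inherits(model, "rf_model"), inherits(map, "sensitivity_map"))
  co <- model$components
  mx <- max(map$values)
  centre_vals <- map_interp(map, co$center_az, co$center_el)
  high <- which(centre_vals > peak_threshold * mx)
  pairs <- list(); profiles <- list()
  coupled <- FALSE
  if (length(high) >= 2L) {
    cmb <- utils::combn(high, 2L)
    for (m in seq_len(ncol(cmb))) {
      i <- cmb[1L, m]; j <- cmb[2L, m]
      tt <- seq(0, 1, length.out = 101L)
      laz <- co$center_az[i] + tt * (co$center_az[j] - co$center_az[i])
      lel <- co$center_el[i] + tt * (co$center_el[j] - co$center_el[i])
      prof <- map_interp(map, laz, lel)
      valley <- min(prof)
      hit <- valley < valley_threshold * mx
      coupled <- coupled || hit
      pairs[[length(pairs) + 1L]] <- data.frame(
        comp_i = i, comp_j = j, peak_i = centre_vals[i],
        peak_j = centre_vals[j], valley = valley, qualifies = hit)
      profiles[[length(profiles) + 1L]] <- prof
    }
  }
  list(coupled = coupled,
       pairs = if (length(pairs)) do.call(rbind, pairs) else NULL,
       profiles = profiles)
}

# ---- response-delay analysis -----------------------------------------------

# assign each grid node to the RF component whose (weighted) Gaussian
# contributes most there
component_territory <- function(model, az, el) {
  co <- model$components
  best <- rep(1L, length(az)); best_val <- rep(-Inf, length(az))
  for (j in seq_len(nrow(co))) {
    val <- gauss2d_component(
      az, el, c(co$amplitude[j], co$center_az[j], co$center_el[j],
                co$sigma_major[j], co$sigma_minor[j],
                co$orientation[j] * pi / 180))
    sel <- val > best_val
    best[sel] <- j; best_val[sel] <- val[sel]
  }
  best
}

#' Response-delay differences between coupled RF components
#'
#' Estimates the time of maximum response for each RF component as the
#' median, over the component's 5 strongest flash epochs, of the epoch
#' peak time relative to flash onset, and reports
#' `delta_t = t_max(main) - t_max(secondary)` for every coupled component,
#' in ms at trace resolution.
#'
#' Per-epoch peak times are located by matched filtering: a response
#' template is first averaged from the main component's strongest epochs,
#' and each epoch's peak time is the lag maximizing its cross-correlation
#' with that template (plus the template's own peak offset). The template
#' is shared by all components, so any template bias cancels in the
#' difference. This is considerably more robust to recording noise than a
#' raw per-epoch argmax, whose jitter on the flat response peak exceeds the
#' millisecond offsets being measured.
#'
#' @param trace The grid-scan [recording_trace()].
#' @param protocol The [grid_scan_protocol()].
#' @param model A fitted `rf_model` with >= 2 components.
#' @param n_epochs Number of strongest epochs per component (default 5).
#' @return Data frame `component, delta_t_ms, t_max_ms, n_epochs_used`
#'   (first row is the main component with `delta_t_ms = 0`); secondary
#'   components lacking usable epochs get `NA`.
#' @export
delay_difference <- function(trace, protocol, model, n_epochs = 5) {
  stopifnot(inherits(model, "rf_model"))
  if (nrow(model$components) < 2L) {
    stop("delay_difference needs a model with >= 2 components", call. = FALSE)
  }
  mk <- trace$markers[trace$markers$kind == "flash", ]
  coords <- grid_coordinates(protocol)
  k <- mk$payload
  rr <- ((k - 1L) %/% protocol$n_cols) + 1L
  cc <- ((k - 1L) %% protocol$n_cols) + 1L
  az <- coords$az_deg[cc]; el <- coords$el_deg[rr]
  terr <- component_territory(model, az, el)
  period_n <- round(protocol$period_ms / 1000 * trace$sampling_rate)
  onset_idx <- round((mk$time_s - trace$t0) * trace$sampling_rate) + 1L
  epoch_of <- function(i) {
    seg <- trace$samples[onset_idx[i]:min(onset_idx[i] + period_n - 1L,
                                          length(trace$samples))]
    if (length(seg) < period_n) {       # trailing epoch: pad with last sample
      seg <- c(seg, rep(seg[length(seg)], period_n - length(seg)))
    }
    seg
  }
  amp <- vapply(seq_len(nrow(mk)), function(i) {
    seg <- epoch_of(i); max(seg) - min(seg)
  }, numeric(1))
  noise_floor <- stats::median(amp)
  strongest <- function(j) {
    cand <- which(terr == j & amp > noise_floor)
    cand[order(amp[cand], decreasing = TRUE)][
      seq_len(min(n_epochs, length(cand)))]
  }
  # template from the main component's strongest epochs (baseline-subtracted)
  main_idx <- strongest(1L)
  if (length(main_idx) < 1L) stop("main component has no usable epochs",
                                  call. = FALSE)
  tpl <- rowMeans(vapply(main_idx, function(i) {
    seg <- epoch_of(i); seg - min(seg)
  }, numeric(period_n)))
  tpl_peak <- which.max(tpl)
  max_lag <- round(0.02 * trace$sampling_rate)   # +/- 20 ms search window
  peak_time_ms <- function(i) {
    seg <- epoch_of(i)
    lags <- (-max_lag):max_lag
    # Pearson correlation per lag over the overlapping window: invariant to
    # baseline offset and window shrinkage, so the argmax is unbiased
    xc <- vapply(lags, function(L) {
      if (L >= 0) {
        n <- period_n - L
        a <- tpl[seq_len(n)]; b <- seg[L + seq_len(n)]
      } else {
        n <- period_n + L
        a <- tpl[-L + seq_len(n)]; b <- seg[seq_len(n)]
      }
      sa <- stats::sd(a); sb <- stats::sd(b)
      if (sa < 1e-12 || sb < 1e-12) return(-Inf)
      stats::cor(a, b)
    }, numeric(1))
    best <- lags[which.max(xc)]
    (tpl_peak - 1L + best) / trace$sampling_rate * 1000
  }
  t_max <- vapply(seq_len(nrow(model$components)), function(j) {
    idx <- strongest(j)
    if (length(idx) < 1L) return(NA_real_)
    stats::median(vapply(idx, peak_time_ms, numeric(1)))
  }, numeric(1))
  n_used <- vapply(seq_len(nrow(model$components)),
                   function(j) length(strongest(j)), integer(1))
  data.frame(
    component = seq_len(nrow(model$components)),
    role = model$components$role,
    t_max_ms = t_max,
    delta_t_ms = t_max[1L] - t_max,
    n_epochs_used = n_used
  )
}

#' Average circular FWHM over repeated recordings of one cell
#'
#' @param models List of `rf_model` objects for the same cell.
#' @return Arithmetic mean of the main component's `fwhm_circ` over
#'   `quality == "high"` models.
#' @export
average_fwhm <- function(models) {
  hq <- Filter(function(m) identical(m$quality, "high"), models)
  if (length(hq) == 0L) stop("not estimable: no high-quality recordings",
                             call. = FALSE)
  mean(vapply(hq, function(m) m$components$fwhm_circ[1L], numeric(1)))
}
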