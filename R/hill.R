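#' Fit a Hill intensity-response function
#'
#' Least-squares fit of the sigmoidal V-log(I) curve
#' `V(I) = v_max * I^n / (I^n + k^n)` to per-flash peak responses.
#' Optimization runs in log-parameter space (all three parameters are
#' positive) with a multi-start over Hill slopes `n` in {0.5, 1, 2}; `k` is
#' initialized at the intensity whose response is nearest half the maximum
#' response, `v_max` at 1.05x the maximum response. The best of the starts
#' is returned.
#'
#' @param intensities Relative intensities (> 0), >= 5 points spanning at
#'   least 2 log10 units.
#' @param responses_mV Peak depolarizations (>= 0), same length.
#' @return An object of class `hill_fit` with fields `v_max`, `k_half`,
#'   `n`, `rss`, `n_points`.
#' @export
fit_hill <- function(intensities, responses_mV) {
  if (length(intensities) != length(responses_mV)) {
    stop("intensities and responses must have equal length", call. = FALSE)
  }
  if (length(intensities) < 5L) {
    stop("need >= 5 intensity-response points", call. = FALSE)
  }
  if (any(intensities <= 0)) stop("intensities must be > 0", call. = FALSE)
  if (any(responses_mV < 0)) stop("responses must be >= 0", call. = FALSE)
  if (diff(range(log10(intensities))) < 2 - 1e-9) {
    stop("intensities must span >= 2 log10 units", call. = FALSE)
  }
  if (diff(range(responses_mV)) < 1e-12) {
    stop("degenerate fit: all responses equal", call. = FALSE)
  }
  vmax0 <- 1.05 * max(responses_mV)
  k0 <- intensities[which.min(abs(responses_mV - max(responses_mV) / 2))]
  obj <- function(p) {
    pred <- hill_response(intensities, exp(p[1]), exp(p[2]), exp(p[3]))
    sum((pred - responses_mV)^2)
  }
  best <- NULL
  for (n0 in c(0.5, 1, 2)) {
    fit <- stats::optim(log(c(vmax0, k0, n0)), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    # polish with Nelder-Mead in case BFGS stalled on a flat region
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-15))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  p <- exp(best$par)
  structure(
    list(v_max = p[1], k_half = p[2], n = p[3], rss = best$value,
         n_points = length(intensities)),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> v_max=%.3f mV, k_half=%.4g, n=%.3f (rss=%.3g, %d pts)\n",
              x$v_max, x$k_half, x$n, x$rss, x$n_points))
  invisible(x)
}

#' Inverse Hill transformation
#'
#' Maps a normalized voltage response r (the measured response as a
#' fraction of `v_max`) back through the Hill
#' nonlinearity to an equivalent relative intensity ("sensitivity")
#' `s(r) = (r / (1 - r))^(1/n)`, in units of the half-maximum intensity
#' (`s(0.5) = 1`). Callers rescale a whole map or series by its maximum so
#' final sensitivities lie in \[0, 1\]. Responses above `r_cap` are clipped
#' before inversion (the inverse diverges as r -> 1); clipping is flagged
#' via the `"clipped"` attribute.
#'
#' @param r Normalized response(s) in `[0, 1)`; values below 0 are an
#'   error.
#' @param hill A `hill_fit` (only the slope `n` is used), or a numeric Hill
#'   slope.
#' @param r_cap Clipping ceiling, default 0.99.
#' @return Equivalent relative intensity (>= 0), with attribute `clipped`
#'   (logical: was any value clipped?).
#' @export
inverse_hill <- function(r, hill, r_cap = 0.99) {
  n <- if (inherits(hill, "hill_fit")) hill$n else as.numeric(hill)
  if (any(r < 0)) stop("normalized responses must be >= 0", call. = FALSE)
  clipped <- any(r > r_cap)
  r <- pmin(r, r_cap)
  s <- (r / (1 - r))^(1 / n)
  attr(s, "clipped") <- clipped
  s
}

#' Extract per-epoch peak amplitudes from a marked trace
#'
#' For each stimulus marker, takes the samples from that marker to the next
#' (or to the end of the trace) and estimates the response amplitude. The
#' default `"peak_baseline"` estimator lightly smooths the epoch (Gaussian,
#' sd `smooth_ms`) and returns the smoothed peak minus the mean of the
#' trailing quarter of the epoch (where the flash response has decayed);
#' unlike a raw `max - min` it carries no extreme-value noise bias, which
#' matters when amplitudes are pushed through the steep inverse Hill
#' transformation. `method = "maxmin"` gives the plain range.
#'
#' @param trace A [recording_trace()] with at least one marker.
#' @param kinds Optional character vector restricting which marker kinds
#'   delimit epochs (default: all markers).
#' @param method `"peak_baseline"` (default) or `"maxmin"`.
#' @param smooth_ms Gaussian smoothing sd in ms for `"peak_baseline"`.
#' @return Data frame `payload, amplitude_mV, t_onset_s`.
#' @export
epoch_amplitudes <- function(trace, kinds = NULL,
                             method = c("peak_baseline", "maxmin"),
                             smooth_ms = 5) {
  method <- match.arg(method)
  mk <- trace$markers
  if (!is.null(kinds)) mk <- mk[mk$kind %in% kinds, ]
  if (nrow(mk) < 1L) stop("trace has no (matching) markers", call. = FALSE)
  idx <- round((mk$time_s - trace$t0) * trace$sampling_rate) + 1L
  ends <- c(idx[-1L] - 1L, length(trace$samples))
  kern <- if (method == "peak_baseline")
    gauss_kernel_1d(smooth_ms / 1000 * trace$sampling_rate) else NULL
  amp <- vapply(seq_len(nrow(mk)), function(i) {
    seg <- trace$samples[idx[i]:ends[i]]
    if (method == "maxmin") return(max(seg) - min(seg))
    sm <- as.numeric(conv_rows_reflect(matrix(seg, nrow = 1L), kern))
    tail_idx <- seq(floor(3 * length(sm) / 4) + 1L, length(sm))
    max(0, max(sm) - mean(sm[tail_idx]))
  }, numeric(1))
  data.frame(payload = mk$payload, amplitude_mV = amp, t_onset_s = mk$time_s)
}

#' Fit the V-log(I) curve of a recorded intensity series
#'
#' Convenience wrapper: extracts per-step peak amplitudes from an
#' intensity-series trace (markers of kind `"intensity"`) and fits the Hill
#' function.
#'
#' @param trace A [recording_trace()] from an intensity-series protocol.
#' @return A `hill_fit`.
#' @export
fit_hill_trace <- function(trace) {
  ep <- epoch_amplitudes(trace, kinds = "intensity")
  fit_hill(ep$payload, ep$amplitude_mV)
}

#' Fit the spectral peak of a visual pigment
#'
#' One-parameter least-squares fit of the A1 template's `lambda_max` to a
#' sensitivity spectrum. Raw voltage responses should first be transformed
#' to sensitivities with [inverse_hill()]; the fitted model includes a free
#' multiplicative scale so that only the spectral shape constrains
#' `lambda_max`.
#'
#' @param wavelengths_nm Wavelengths (>= 5), nm, within \[300, 700\].
#' @param sensitivities Relative sensitivities (>= 0), or raw per-flash
#'   peak responses in mV when `hill` is supplied.
#' @param hill Optional `hill_fit`; when given, `sensitivities` are taken
#'   as voltage responses and passed through [inverse_hill()] first.
#' @return An object of class `spectral_fit` with `lambda_max` and `rss`.
#' @export
fit_spectral_peak <- function(wavelengths_nm, sensitivities, hill = NULL) {
  if (length(wavelengths_nm) < 5L) stop("need >= 5 wavelengths",
                                        call. = FALSE)
  if (!is.null(hill)) {
    sensitivities <- as.numeric(
      inverse_hill(sensitivities / hill$v_max, hill))
  }
  if (any(wavelengths_nm < 300 | wavelengths_nm > 700)) {
    stop("wavelengths outside template support [300, 700] nm", call. = FALSE)
  }
  if (stats::sd(sensitivities) < 1e-12 * max(abs(sensitivities), 1)) {
    stop("degenerate fit: flat spectrum", call. = FALSE)
  }
  rss_at <- function(lmax) {
    tpl <- spectral_template(wavelengths_nm, lmax)
    sc <- sum(tpl * sensitivities) / sum(tpl^2)   # optimal scale, closed form
    sum((sensitivities - sc * tpl)^2)
  }
  opt <- stats::optimize(rss_at, interval = c(310, 650), tol = 1e-4)
  structure(list(lambda_max = opt$minimum, rss = opt$objective),
            class = "spectral_fit")
}
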