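#' Average repeated polarizer series
#'
#' When several polarizer sweeps were recorded from one cell, the per-angle
#' arithmetic mean of the raw mV responses is taken first, before any
#' sensitivity transformation.
#'
#' @param repeats List of data frames, each with columns `angle_deg` and
#'   `response_mV`, all sharing the same angle comb.
#' @return A single data frame `angle_deg, response_mV`.
#' @export
average_repeats <- function(repeats) {
  stopifnot(length(repeats) >= 1L)
  ref <- repeats[[1L]]$angle_deg
  for (r in repeats) {
    if (length(r$angle_deg) != length(ref) ||
        any(abs(r$angle_deg - ref) > 1e-9)) {
      stop("repeats must share the same angle comb", call. = FALSE)
    }
  }
  resp <- rowMeans(vapply(repeats, function(r) r$response_mV,
                          numeric(length(ref))))
  data.frame(angle_deg = ref, response_mV = resp)
}

# Least-squares fit of s(phi) = A + B*cos(2*(phi - phi_max)) via the linear
# reparameterization A + Bc*cos(2 phi) + Bs*sin(2 phi); exact for the
# cos^2-with-floor tuning model.
fit_cos2 <- function(angles_deg, sensitivities) {
  phi <- angles_deg * pi / 180
  X <- cbind(1, cos(2 * phi), sin(2 * phi))
  cf <- stats::lm.fit(X, sensitivities)$coefficients
  b <- sqrt(cf[2]^2 + cf[3]^2)
  phi_max <- (atan2(cf[3], cf[2]) / 2 * 180 / pi) %% 180
  list(mean = unname(cf[1]), modulation = unname(b),
       phi_max = unname(phi_max))
}

#' Compute polarization sensitivity and preferred angle
#'
#' Transforms the per-angle mV responses to relative sensitivities via the
#' inverse Hill transformation (using the cell's own V-log(I) fit), then
#' computes PS as the ratio between maximum and minimum sensitivity across
#' e-vector angles, and the preferred angle `phi_max` as the maximum of a
#' least-squares cos^2-model fit (finer than the sampling comb).
#'
#' Exclusion rules: a measurement is flagged `excluded` when the mean PS
#' exceeds `ps_cap` (default 20; such ratios arise from near-zero or
#' hyperpolarizing minima and are treated as artefactual) or when any
#' normalized response is non-positive after baseline handling.
#'
#' @param series Data frame `angle_deg, response_mV` (>= 8 angles spanning
#'   180 deg less one step), typically from [average_repeats()] or
#'   [epoch_amplitudes()] of a polarizer trace.
#' @param hill A `hill_fit` for the same cell.
#' @param ps_cap Exclusion cap on PS (default 20).
#' @param rf_tag Optional label of the RF component the series was aligned
#'   to (`"main"`, `"secondary1"`, ...), carried through unchanged.
#' @return An object of class `ps_measurement`: `angles_deg`,
#'   `sensitivities` (rescaled to max 1), `ps`, `phi_max` (deg mod 180, or
#'   `NA` when not estimable), `excluded`, `exclusion_reason`, `rf_tag`.
#' @export
compute_ps <- function(series, hill, ps_cap = 20, rf_tag = "main") {
  stopifnot(is.data.frame(series),
            all(c("angle_deg", "response_mV") %in% names(series)))
  if (nrow(series) < 8L) stop("need >= 8 polarizer angles", call. = FALSE)
  if (diff(range(series$angle_deg)) < 180 - diff(series$angle_deg)[1] - 1e-9) {
    stop("angles must span >= 180 deg (less one step)", call. = FALSE)
  }
  out <- list(angles_deg = series$angle_deg, sensitivities = NULL,
              ps = NA_real_, phi_max = NA_real_, excluded = FALSE,
              exclusion_reason = NA_character_, rf_tag = rf_tag)
  class(out) <- "ps_measurement"
  if (any(series$response_mV <= 0)) {
    out$excluded <- TRUE
    out$exclusion_reason <- "non-positive minimum"
    return(out)
  }
  r <- series$response_mV / hill$v_max
  s <- inverse_hill(r, hill)
  out$sensitivities <- as.numeric(s / max(s))
  out$ps <- max(s) / min(s)
  if (out$ps > 1 + 1e-9) {
    out$phi_max <- fit_cos2(series$angle_deg, out$sensitivities)$phi_max
  }
  if (out$ps > ps_cap) {
    out$excluded <- TRUE
    out$exclusion_reason <- sprintf("artefactual (PS > cap %g)", ps_cap)
  }
  out
}

#' @export
print.ps_measurement <- function(x, ...) {
  cat(sprintf("<ps_measurement> PS=%.3f, phi_max=%s deg%s\n",
              x$ps,
              if (is.na(x$phi_max)) "NA" else sprintf("%.1f", x$phi_max),
              if (x$excluded) paste0(" [EXCLUDED: ", x$exclusion_reason, "]")
              else ""))
  invisible(x)
}

#' Axial offset between two preferred e-vector angles
#'
#' E-vector angles are axial (mod 180 deg); the offset is the smallest
#' angular difference between the two axes, folded to \[0, 90\] deg.
#'
#' @param a,b `ps_measurement` objects (neither excluded nor lacking
#'   `phi_max`), or plain angles in degrees.
#' @return Offset in degrees, in \[0, 90\].
#' @export
phi_max_offset <- function(a, b) {
  get_phi <- function(x) {
    if (inherits(x, "ps_measurement")) {
      if (isTRUE(x$excluded)) stop("excluded PS measurement", call. = FALSE)
      x <- x$phi_max
    }
    if (is.na(x)) stop("phi_max missing / not estimable", call. = FALSE)
    x
  }
  d <- abs(get_phi(a) - get_phi(b)) %% 180
  min(d, 180 - d)
}
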