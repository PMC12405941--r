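#' Construct a recording trace
#'
#' A `recording_trace` is a uniformly sampled membrane-potential time series
#' from one intracellular photoreceptor recording, together with the stimulus
#' event markers (flash onsets, polarizer angles, intensity steps) needed to
#' cut the trace into stimulus epochs.
#'
#' @param samples Numeric vector of membrane potential in mV, uniformly
#'   sampled. Must be finite.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param markers Data frame with columns `time_s` (event time in seconds),
#'   `kind` (character event label, e.g. `"flash"`) and `payload` (numeric
#'   event payload: grid position index, polarizer angle in degrees, or
#'   relative flash intensity). Markers must be sorted by time and fall
#'   within the trace duration.
#'
#' @return An object of class `recording_trace`.
#' @export
recording_trace <- function(samples, sampling_rate, t0 = 0, markers = NULL) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number (Hz)", call. = FALSE)
  }
  if (is.null(markers)) {
    markers <- data.frame(time_s = numeric(0), kind = character(0),
                          payload = numeric(0))
  }
  if (!all(c("time_s", "kind", "payload") %in% names(markers))) {
    stop("`markers` needs columns time_s, kind, payload", call. = FALSE)
  }
  markers <- markers[, c("time_s", "kind", "payload")]
  if (nrow(markers) > 0L) {
    if (is.unsorted(markers$time_s)) {
      stop("markers must be sorted by time", call. = FALSE)
    }
    t_end <- t0 + length(samples) / sampling_rate
    if (any(markers$time_s < t0 - 1e-12) || any(markers$time_s > t_end + 1e-12)) {
      stop("markers must lie within the trace duration", call. = FALSE)
    }
  }
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         t0 = as.numeric(t0),
         markers = markers),
    class = "recording_trace"
  )
}

#' @export
print.recording_trace <- function(x, ...) {
  cat(sprintf("<recording_trace> %d samples @ %g Hz (%.3f s), %d markers\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, nrow(x$markers)))
  invisible(x)
}

#' Sample times of a recording trace
#'
#' @param trace A [recording_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1L) / trace$sampling_rate
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read a voltage trace from CSV
#'
#' Reads a plain-text trace in the interchange format `time_s,voltage_mV`.
#' A companion JSON sidecar (same path with the extension `.json`) supplies
#' `sampling_rate`, `t0` and the stimulus `markers`; when the sidecar is
#' absent the sampling rate is inferred from the time column and the marker
#' list is empty.
#'
#' Time stamps must be strictly increasing and uniform to within 1e-6 s;
#' the trace is never resampled.
#'
#' @param path Path to the CSV file.
#' @return A [recording_trace()].
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, colClasses = "numeric"),
    error = function(e) stop("trace format error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (!all(c("time_s", "voltage_mV") %in% names(df))) {
    stop("trace format error: columns time_s,voltage_mV required",
         call. = FALSE)
  }
  if (nrow(df) < 2L) {
    stop("trace format error: need at least two samples", call. = FALSE)
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("trace data error: time not strictly increasing",
                         call. = FALSE)
  if (max(dt) - min(dt) > 1e-6) {
    stop("trace data error: non-uniform sampling (jitter > 1e-6 s)",
         call. = FALSE)
  }
  side <- sidecar_path(path)
  sampling_rate <- 1 / stats::median(dt)
  t0 <- df$time_s[1L]
  markers <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$sampling_rate)) sampling_rate <- meta$sampling_rate
    if (!is.null(meta$t0)) t0 <- meta$t0
    if (!is.null(meta$markers) && length(meta$markers)) {
      markers <- as.data.frame(meta$markers)
    }
  }
  recording_trace(df$voltage_mV, sampling_rate, t0, markers)
}

#' Write a voltage trace to CSV (+ JSON sidecar)
#'
#' @param trace A [recording_trace()].
#' @param path Output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "recording_trace"))
  df <- data.frame(time_s = trace_times(trace), voltage_mV = trace$samples)
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(sampling_rate = trace$sampling_rate, t0 = trace$t0,
         markers = trace$markers),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Grid-scan stimulus protocol
#'
#' Describes the receptive-field mapping protocol: a small UV square flashed
#' at every node of a regular angular grid, scanning row-major left-to-right
#' then top-to-bottom. Defaults correspond to a 20 deg x 20 deg grid at
#' 1 deg steps (21 x 21 positions), a 0.9 deg x 0.9 deg stimulus, 20 ms
#' flashes repeated every 145 ms.
#'
#' @param extent_deg Angular span of the grid on each axis (deg).
#' @param step_deg Grid step (deg).
#' @param flash_ms Flash duration (ms); must be shorter than `period_ms`.
#' @param period_ms Inter-flash period (ms); one epoch per grid node.
#' @param stim_size_deg Side of the square stimulus (deg).
#' @return An object of class `grid_scan_protocol` with derived fields
#'   `n_cols`, `n_rows` and `scan_order = "row-major"`.
#' @export
grid_scan_protocol <- function(extent_deg = 20, step_deg = 1, flash_ms = 20,
                               period_ms = 145, stim_size_deg = 0.9) {
  vals <- c(extent_deg, step_deg, flash_ms, period_ms, stim_size_deg)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all protocol values must be positive", call. = FALSE)
  }
  if (flash_ms >= period_ms) {
    stop("flash_ms must be < period_ms", call. = FALSE)
  }
  n <- floor(extent_deg / step_deg) + 1L
  structure(
    list(extent_deg = extent_deg, step_deg = step_deg,
         n_cols = n, n_rows = n,
         flash_ms = flash_ms, period_ms = period_ms,
         stim_size_deg = stim_size_deg, scan_order = "row-major"),
    class = "grid_scan_protocol"
  )
}

#' Angular coordinates of the protocol grid
#'
#' Position (row r, col c) maps to azimuth `az_left + (c-1)*step` and
#' elevation `el_top - (r-1)*step`: the top row has the highest elevation,
#' matching a scan that moves left to right, then top to bottom. The grid is
#' centred on (0, 0).
#'
#' @param protocol A [grid_scan_protocol()].
#' @return List with `az_deg` (length `n_cols`, increasing) and `el_deg`
#'   (length `n_rows`, decreasing).
#' @export
grid_coordinates <- function(protocol) {
  half <- protocol$extent_deg / 2
  list(
    az_deg = -half + (seq_len(protocol$n_cols) - 1L) * protocol$step_deg,
    el_deg = half - (seq_len(protocol$n_rows) - 1L) * protocol$step_deg
  )
}

#' Spatial sensitivity map
#'
#' A matrix of per-position response (or sensitivity) values on the scan
#' grid, at one of three processing stages: `"raw"` (max - min voltage per
#' epoch, mV), `"smoothed"` (after Gaussian filtering, mV) or
#' `"sensitivity"` (after the inverse Hill transformation, normalized so the
#' maximum is 1).
#'
#' Rows are ordered top elevation first, matching the scan order.
#'
#' @param values Numeric `n_rows x n_cols` matrix, nonnegative.
#' @param stage One of `"raw"`, `"smoothed"`, `"sensitivity"`.
#' @param az_deg,el_deg Per-column / per-row angular coordinates (deg).
#' @return An object of class `sensitivity_map`.
#' @export
sensitivity_map <- function(values, stage = c("raw", "smoothed", "sensitivity"),
                            az_deg = NULL, el_deg = NULL) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("map values must be finite", call. = FALSE)
  if (min(values) < 0) stop("map values must be nonnegative", call. = FALSE)
  if (is.null(az_deg)) az_deg <- seq_len(ncol(values)) - 1 - (ncol(values) - 1) / 2
  if (is.null(el_deg)) el_deg <- rev(seq_len(nrow(values)) - 1 - (nrow(values) - 1) / 2)
  if (length(az_deg) != ncol(values) || length(el_deg) != nrow(values)) {
    stop("coordinate lengths must match map dimensions", call. = FALSE)
  }
  if (stage == "sensitivity") {
    if (abs(max(values) - 1) > 1e-6) {
      stop("sensitivity-stage map must have max = 1", call. = FALSE)
    }
  }
  structure(
    list(values = unname(values), stage = stage,
         az_deg = as.numeric(az_deg), el_deg = as.numeric(el_deg)),
    class = "sensitivity_map"
  )
}

#' @export
print.sensitivity_map <- function(x, ...) {
  cat(sprintf("<sensitivity_map> stage=%s %dx%d, max=%.4g\n",
              x$stage, nrow(x$values), ncol(x$values), max(x$values)))
  invisible(x)
}

#' Write / read a sensitivity map (CSV + JSON header)
#'
#' The CSV holds `n_rows` lines of `n_cols` comma-separated values, top row
#' first, at full double precision (lossless round trip). The JSON sidecar
#' records the stage, grid coordinates and declared dimensions; on read the
#' declared dimensions and (for sensitivity-stage maps) the max = 1
#' normalization invariant are verified.
#'
#' @param map A [sensitivity_map()].
#' @param path CSV path (sidecar written/read at the same path with `.json`).
#' @return `write_map_csv`: `path` invisibly; `read_map_csv`: the map.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "sensitivity_map"))
  lines <- apply(map$values, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, path)
  jsonlite::write_json(
    list(stage = map$stage, n_rows = nrow(map$values),
         n_cols = ncol(map$values), az_deg = map$az_deg,
         el_deg = map$el_deg),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  rows <- lapply(strsplit(lines, ","), as.numeric)
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1L) {
    stop("map format error: ragged rows", call. = FALSE)
  }
  values <- do.call(rbind, rows)
  side <- sidecar_path(path)
  stage <- "raw"
  az <- NULL; el <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$n_rows) &&
        (meta$n_rows != nrow(values) || meta$n_cols != ncol(values))) {
      stop(sprintf(
        "map format error: declared %dx%d but file holds %dx%d",
        meta$n_rows, meta$n_cols, nrow(values), ncol(values)), call. = FALSE)
    }
    if (!is.null(meta$stage)) stage <- meta$stage
    az <- meta$az_deg; el <- meta$el_deg
  }
  sensitivity_map(values, stage = stage, az_deg = az, el_deg = el)
}

#' One cell's derived profile
#'
#' Bundles the quantities that feed the group statistics: species, eye
#' region, polarization sensitivity (PS), preferred e-vector angle, circular
#' FWHM of the main receptive-field component, coupling flag and the Hill
#' fit.
#'
#' @param cell_id Character identifier.
#' @param species `"Apis"` or `"Bombus"`.
#' @param eye_region `"main_retina"`, `"marginal_DRA"` or `"DRA"`.
#' @param ps Polarization sensitivity (max/min sensitivity ratio, >= 1), or
#'   `NA` when excluded/not measured.
#' @param phi_max Preferred e-vector angle, degrees in \[0, 180).
#' @param fwhm_circ Equal-area circular FWHM of the main RF (deg, > 0).
#' @param coupled Logical: does the cell show coupled secondary RFs?
#' @param hill Optional [fit_hill()] result.
#' @param lambda_max Spectral peak (nm), optional.
#' @param ps_excluded Logical exclusion flag for the PS measurement.
#' @return An object of class `cell_record` (a one-row-like list).
#' @export
cell_record <- function(cell_id, species, eye_region, ps = NA_real_,
                        phi_max = NA_real_, fwhm_circ = NA_real_,
                        coupled = FALSE, hill = NULL,
                        lambda_max = NA_real_, ps_excluded = FALSE) {
  species <- match.arg(species, c("Apis", "Bombus"))
  eye_region <- match.arg(eye_region, c("main_retina", "marginal_DRA", "DRA"))
  if (!is.na(ps) && ps < 1) stop("ps must be >= 1", call. = FALSE)
  if (!is.na(fwhm_circ) && fwhm_circ <= 0) stop("fwhm_circ must be > 0",
                                                call. = FALSE)
  if (!is.na(phi_max)) phi_max <- phi_max %% 180
  structure(
    list(cell_id = as.character(cell_id), species = species,
         eye_region = eye_region, ps = ps, phi_max = phi_max,
         fwhm_circ = fwhm_circ, coupled = isTRUE(coupled), hill = hill,
         lambda_max = lambda_max, ps_excluded = isTRUE(ps_excluded)),
    class = "cell_record"
  )
}

#' Collect cell records into the statistics table
#'
#' @param records List of [cell_record()] objects.
#' @return Data frame with columns `cell_id, species, eye_region, ps,
#'   phi_max, fwhm_circ, coupled, excluded`.
#' @export
cells_table <- function(records) {
  stopifnot(length(records) > 0L)
  do.call(rbind, lapply(records, function(r) {
    data.frame(cell_id = r$cell_id, species = r$species,
               eye_region = r$eye_region, ps = r$ps, phi_max = r$phi_max,
               fwhm_circ = r$fwhm_circ, coupled = r$coupled,
               excluded = r$ps_excluded, stringsAsFactors = FALSE)
  }))
}
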