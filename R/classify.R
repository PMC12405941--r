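#' Eye-region classification rule
#'
#' Thresholds for assigning a recorded cell to main retina, marginal DRA or
#' DRA. Recording-depth metadata, when present, always decides (the
#' topological criterion); numeric criteria corroborate it or vote in its
#' absence:
#' * polarization sensitivity: PS below `ps_high` points to the main
#'   retina, above it to the (marginal) DRA;
#' * absolute light sensitivity: DRA cells are roughly an order of
#'   magnitude less sensitive, i.e. their Hill `k_half` sits about
#'   `sensitivity_ratio` times higher than main-retina cells; a cell is
#'   called "high sensitivity" when `k_half < k_half_ref *
#'   sqrt(sensitivity_ratio)`;
#' * receptive-field size: circular FWHM at or above `fwhm_large_deg`
#'   points to the DRA.
#'
#' The thresholds are package defaults calibrated to typical group
#' contrasts, not measured constants.
#'
#' @param ps_high PS threshold separating low from high PS (default 4).
#' @param sensitivity_ratio Fold difference in `k_half` between DRA and
#'   main retina (default 10).
#' @param k_half_ref Reference main-retina `k_half` in relative intensity
#'   units (default 0.1).
#' @param fwhm_large_deg Circular FWHM (deg) above which an RF counts as
#'   DRA-sized (default 5).
#' @return An object of class `classification_rule`.
#' @export
classification_rule <- function(ps_high = 4, sensitivity_ratio = 10,
                                k_half_ref = 0.1, fwhm_large_deg = 5) {
  stopifnot(ps_high > 0, sensitivity_ratio > 0, k_half_ref > 0,
            fwhm_large_deg > 0)
  structure(list(ps_high = ps_high, sensitivity_ratio = sensitivity_ratio,
                 k_half_ref = k_half_ref, fwhm_large_deg = fwhm_large_deg),
            class = "classification_rule")
}

#' Classify a cell into an eye region
#'
#' Applies the multi-criterion rule of [classification_rule()]. If a depth
#' hint is given it decides, and disagreeing numeric criteria are reported
#' as consistency warnings in the rationale; otherwise the available
#' numeric criteria vote: high PS and high sensitivity together indicate
#' the marginal DRA, high PS with low sensitivity the DRA, and a majority
#' of main-retina-like criteria the main retina. At least two criteria
#' (depth hint, Hill fit, PS, FWHM) must be present.
#'
#' @param ps Polarization sensitivity, or `NA`.
#' @param k_half Hill half-maximum intensity (relative units), or `NA`.
#' @param fwhm_circ Circular FWHM of the main RF (deg), or `NA`.
#' @param depth_hint Optional region label from recording depth
#'   (`"main_retina"`, `"marginal_DRA"`, `"DRA"`), or `NA`.
#' @param rule A [classification_rule()].
#' @return List: `eye_region`, `rationale` (character trace of every
#'   criterion consulted), `warnings` (consistency notes).
#' @export
classify_cell <- function(ps = NA, k_half = NA, fwhm_circ = NA,
                          depth_hint = NA, rule = classification_rule()) {
  have <- c(depth = !is.na(depth_hint), ps = !is.na(ps),
            hill = !is.na(k_half), fwhm = !is.na(fwhm_circ))
  if (sum(have) < 2L) {
    stop("not classifiable: fewer than two criteria available",
         call. = FALSE)
  }
  rationale <- character(0)
  k_split <- rule$k_half_ref * sqrt(rule$sensitivity_ratio)
  high_ps <- if (have["ps"]) ps >= rule$ps_high else NA
  high_sens <- if (have["hill"]) k_half < k_split else NA
  large_rf <- if (have["fwhm"]) fwhm_circ >= rule$fwhm_large_deg else NA
  if (have["ps"]) {
    rationale <- c(rationale, sprintf(
      "PS = %.2f is %s ps_high = %g (%s-like)", ps,
      if (high_ps) ">=" else "<", rule$ps_high,
      if (high_ps) "DRA" else "main retina"))
  }
  if (have["hill"]) {
    rationale <- c(rationale, sprintf(
      "k_half = %.3g is %s split %.3g (%s sensitivity: %s-like)", k_half,
      if (high_sens) "<" else ">=", k_split,
      if (high_sens) "high" else "low",
      if (high_sens) "main retina / marginal DRA" else "DRA"))
  }
  if (have["fwhm"]) {
    rationale <- c(rationale, sprintf(
      "FWHM = %.2f deg is %s fwhm_large = %g deg (%s-like)", fwhm_circ,
      if (large_rf) ">=" else "<", rule$fwhm_large_deg,
      if (large_rf) "DRA" else "main retina"))
  }
  vote_label <- function() {
    votes_dra <- sum(c(isTRUE(high_ps), isTRUE(!high_sens),
                       isTRUE(large_rf)))
    votes_main <- sum(c(isTRUE(!high_ps), isTRUE(high_sens),
                        isTRUE(!large_rf)))
    if (isTRUE(high_ps) && isTRUE(high_sens)) return("marginal_DRA")
    if (votes_dra > votes_main) "DRA" else "main_retina"
  }
  warnings <- character(0)
  if (have["depth"]) {
    depth_hint <- match.arg(depth_hint,
                            c("main_retina", "marginal_DRA", "DRA"))
    rationale <- c(rationale,
                   sprintf("depth hint '%s' takes precedence", depth_hint))
    if (sum(have) > 1L) {
      numeric_label <- tryCatch(vote_label(), error = function(e) NA)
      if (!is.na(numeric_label) && numeric_label != depth_hint) {
        warnings <- c(warnings, sprintf(
          "numeric criteria vote '%s' but depth hint says '%s'",
          numeric_label, depth_hint))
      }
    }
    return(list(eye_region = depth_hint, rationale = rationale,
                warnings = warnings))
  }
  label <- vote_label()
  rationale <- c(rationale, sprintf("majority vote: %s", label))
  list(eye_region = label, rationale = rationale, warnings = warnings)
}
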