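#' CT enhancement calibration
#'
#' Iodine concentration in blood relates linearly to CT enhancement; the
#' proportionality depends on tube voltage (attenuation per mg I/mL rises
#' as the beam energy approaches the iodine k-edge, so the 80 kV
#' coefficient exceeds the 120 kV one). The coefficient is the one free
#' scale factor of the simulator and is deliberately a configuration
#' value; [calibrate_enhancement()] fits it from measured pairs.
#'
#' @param hu_per_mg_ml named numeric vector or list, HU per (mg I/mL)
#'   keyed by tube voltage in kV.
#' @param baseline_hu unenhanced background attenuation, HU.
#' @return An object of class `enhancement_calibration`.
#' @export
#' @examples
#' enhancement_calibration()
enhancement_calibration <- function(hu_per_mg_ml = c(`80` = 40, `120` = 25),
                                    baseline_hu = 50) {
  k <- unlist(hu_per_mg_ml)
  if (is.null(names(k)) || any(names(k) == ""))
    stop("hu_per_mg_ml must be keyed by tube voltage (kV)", call. = FALSE)
  if (any(k <= 0))
    stop("calibration error: hu_per_mg_ml must be > 0", call. = FALSE)
  if (baseline_hu < 0)
    stop("calibration error: baseline_hu must be >= 0", call. = FALSE)
  structure(list(hu_per_mg_ml = k, baseline_hu = baseline_hu),
            class = "enhancement_calibration")
}

calib_coefficient <- function(calib, kv) {
  key <- as.character(kv)
  if (!key %in% names(calib$hu_per_mg_ml))
    stop(sprintf(
      "calibration error: no coefficient for %s kV (available: %s kV)",
      key, paste(names(calib$hu_per_mg_ml), collapse = ", ")),
      call. = FALSE)
  unname(calib$hu_per_mg_ml[[key]])
}

#' Convert a concentration curve to a time-density curve
#'
#' Applies the linear, origin-preserving concentration-to-enhancement map
#' at the given tube voltage and adds the unenhanced baseline:
#' `attenuation(t) = k(kV) * concentration(t) + baseline`.
#'
#' @param curve a [simulate_contrast()] result.
#' @param calib an [enhancement_calibration()].
#' @param kv tube voltage, kV; must be present in the calibration.
#' @param tap which output tap to convert (default: first).
#' @return A [tdc()] with label `"simulated"` and the calibration baseline.
#' @export
concentration_to_hu <- function(curve, calib = enhancement_calibration(),
                                kv = curve$protocol$tube_voltage,
                                tap = colnames(curve$concentration)[1L]) {
  stopifnot(inherits(curve, "concentration_curve"))
  k <- calib_coefficient(calib, kv)
  tdc(time = curve$time,
      attenuation = k * curve$concentration[, tap] + calib$baseline_hu,
      label = "simulated", baseline = calib$baseline_hu)
}

#' Recover concentration from a time-density curve
#'
#' Exact inverse of [concentration_to_hu()]:
#' `concentration(t) = (attenuation(t) - baseline) / k(kV)`.
#'
#' @param curve a [tdc()].
#' @inheritParams concentration_to_hu
#' @return Numeric vector of iodine concentrations, mg I/mL.
#' @export
hu_to_concentration <- function(curve, calib = enhancement_calibration(),
                                kv) {
  stopifnot(inherits(curve, "tdc"))
  k <- calib_coefficient(calib, kv)
  (curve$attenuation - calib$baseline_hu) / k
}

#' Fit the enhancement coefficient from measured pairs
#'
#' Ordinary least squares of attenuation on concentration; the slope is
#' the HU-per-(mg I/mL) coefficient and the intercept the baseline.
#'
#' @param concentration iodine concentrations, mg I/mL.
#' @param hu measured attenuations, HU.
#' @return List with `hu_per_mg_ml`, `baseline_hu` and the fitted `lm`.
#' @export
#' @examples
#' conc <- c(0, 2, 5, 10)
#' calibrate_enhancement(conc, 40 * conc + 50)$hu_per_mg_ml
calibrate_enhancement <- function(concentration, hu) {
  if (length(concentration) != length(hu) || length(hu) < 2L)
    stop("need at least two (concentration, HU) pairs of equal length",
         call. = FALSE)
  fit <- stats::lm(hu ~ concentration)
  list(hu_per_mg_ml = unname(stats::coef(fit)[2L]),
       baseline_hu = unname(stats::coef(fit)[1L]),
       fit = fit)
}
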