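#' Patient profile
#'
#' Constructs a validated patient profile carrying the three body
#' parameters that drive all physiological scaling in the model: sex,
#' height and weight. Age is carried as metadata only and never enters a
#' formula.
#'
#' @param sex `"male"` or `"female"`.
#' @param height standing height in cm, in \[100, 230\].
#' @param weight body mass in kg, in \[25, 250\].
#' @param age years; optional metadata.
#' @param id opaque patient label.
#' @return An object of class `patient_profile`.
#' @export
#' @examples
#' patient_profile("male", 170, 75)
patient_profile <- function(sex, height, weight, age = NA_real_, id = NULL) {
  if (length(sex) != 1L || !sex %in% c("male", "female"))
    stop("invalid 'sex': must be \"male\" or \"female\"", call. = FALSE)
  check_range(height, "height", 100, 230, "cm")
  check_range(weight, "weight", 25, 250, "kg")
  structure(
    list(sex = sex, height = as.numeric(height),
         weight = as.numeric(weight), age = as.numeric(age),
         id = if (is.null(id)) NA_character_ else as.character(id)),
    class = "patient_profile")
}

check_range <- function(x, field, lo, hi, unit) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("invalid '%s': must be a single value in [%g, %g] %s",
                 field, lo, hi, unit), call. = FALSE)
  invisible(x)
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("<patient_profile> %s, %g cm, %g kg%s\n", x$sex, x$height,
              x$weight,
              if (is.na(x$id)) "" else paste0(" (id: ", x$id, ")")))
  invisible(x)
}

#' Total blood volume from sex, height and weight
#'
#' Sex-specific anthropometric regression on height cubed and weight
#' (Nadler's formula), returning total blood volume in mL. Strictly
#' increasing in both height and weight; the sex-specific constants give
#' males a larger volume than females at equal stature.
#'
#' @param profile a [patient_profile()].
#' @param config model configuration; only the `blood_volume` block is used.
#' @return Total blood volume in mL.
#' @export
#' @examples
#' compute_blood_volume(patient_profile("male", 170, 75))
compute_blood_volume <- function(profile, config = default_config()) {
  stopifnot(inherits(profile, "patient_profile"))
  k <- config$blood_volume[[profile$sex]]
  h_m <- profile$height / 100
  1000 * (k$h3 * h_m^3 + k$w * profile$weight + k$intercept)
}

#' Cardiac output from body weight
#'
#' Allometric scaling from a reference adult:
#' `CO = CO_ref * (W / W_ref)^0.75`, returned in mL/s. The reference output
#' (default 6500 mL/min at 70 kg) and the exponent are configuration
#' values.
#'
#' @inheritParams compute_blood_volume
#' @return Cardiac output in mL/s.
#' @export
compute_cardiac_output <- function(profile, config = default_config()) {
  stopifnot(inherits(profile, "patient_profile"))
  co <- config$cardiac_output
  (co$reference_ml_per_min / 60) *
    (profile$weight / co$reference_weight_kg)^co$exponent
}

#' Patient-specific circulatory parameters
#'
#' Scales the configured reference-man fractions to one patient: regional
#' blood flows are cardiac output times the compartment's through-flow
#' fraction, regional blood volumes are total blood volume times the
#' compartment's volume fraction, and organ extracellular volumes scale
#' with body weight.
#'
#' Two conservation properties hold by construction and are validated on
#' the configuration: the parallel systemic branch flows sum to cardiac
#' output, and the compartment blood volumes sum to total blood volume.
#'
#' @inheritParams compute_blood_volume
#' @return An object of class `body_parameters`: a list with
#'   `total_blood_volume` (mL), `cardiac_output` (mL/s), `regional_flow`
#'   (named vector, mL/s through-flow per compartment),
#'   `regional_blood_volume` (named vector, mL), `extracellular_volume`
#'   (named vector, mL, organ compartments only) and the originating
#'   `profile`.
#' @export
#' @examples
#' bp <- compute_body_parameters(patient_profile("male", 170, 75))
#' bp$cardiac_output
compute_body_parameters <- function(profile, config = default_config()) {
  stopifnot(inherits(profile, "patient_profile"))
  validate_config(config)
  bv <- compute_blood_volume(profile, config)
  co <- compute_cardiac_output(profile, config)
  comps <- config$compartments
  nm <- names(comps)

  inflow_frac <- stats::setNames(numeric(length(nm)), nm)
  for (cn in nm)
    for (e in comps[[cn]]$outflows)
      inflow_frac[[e$target]] <- inflow_frac[[e$target]] + e$fraction

  organs <- nm[vapply(comps, function(cp) identical(cp$kind, "organ"),
                      logical(1))]
  ecv <- vapply(comps[organs], function(cp) cp$ecv_ml_per_kg, numeric(1)) *
    profile$weight

  structure(list(
    total_blood_volume = bv,
    cardiac_output = co,
    regional_flow = co * inflow_frac,
    regional_blood_volume =
      bv * vapply(comps, function(cp) cp$volume_fraction, numeric(1)),
    extracellular_volume = ecv,
    profile = profile
  ), class = "body_parameters")
}

#' @export
print.body_parameters <- function(x, ...) {
  cat(sprintf(
    "<body_parameters> %s, %g cm, %g kg\n  blood volume: %.0f mL\n  cardiac output: %.1f mL/s (%.2f L/min)\n  compartments: %d\n",
    x$profile$sex, x$profile$height, x$profile$weight,
    x$total_blood_volume, x$cardiac_output, x$cardiac_output * 60 / 1000,
    length(x$regional_blood_volume)))
  invisible(x)
}
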