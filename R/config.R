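#' Default model configuration
#'
#' Returns the full default configuration of the simulator as a plain list:
#' anthropometric blood-volume formula constants, allometric cardiac-output
#' scaling, the whole-body circulatory topology (compartments, blood-volume
#' fractions, flow fractions on edges, permeability-surface products,
#' extracellular volumes), and the CT enhancement calibration.
#'
#' All values that the underlying clinical model never fixes numerically
#' (organ flow/volume fractions, exchange rates, the HU-per-concentration
#' coefficient) live here rather than in code, so every physiological
#' assumption is explicit, auditable and swappable via [write_config()] /
#' [read_config()] without touching the implementation. Fractions are taken
#' from standard reference-man physiology and are assumptions, not fitted
#' quantities.
#'
#' Units: time s, volume mL, flow mL/s, concentration mg iodine / mL,
#' attenuation HU. `reference_ml_per_min` is the single boundary value in
#' minutes; it is converted on use.
#'
#' @return A nested list with components `blood_volume`, `cardiac_output`,
#'   `injection_site`, `output_taps`, `compartments`, `calibration`.
#' @seealso [compute_body_parameters()], [build_model()]
#' @export
#' @examples
#' cfg <- default_config()
#' names(cfg$compartments)
default_config <- function() {
  list(
    config_version = "1.0",
    blood_volume = list(
      formula = "nadler",
      # litres; height in metres inside the formula
      male = list(h3 = 0.3669, w = 0.03219, intercept = 0.6041),
      female = list(h3 = 0.3561, w = 0.03308, intercept = 0.1833)
    ),
    cardiac_output = list(
      reference_ml_per_min = 6500,
      reference_weight_kg = 70,
      exponent = 0.75
    ),
    injection_site = "peripheral_vein",
    output_taps = "cerebral_artery",
    compartments = list(
      peripheral_vein = list(
        kind = "vascular", n_sub = 4L, volume_fraction = 0.002,
        outflows = list(list(target = "svc", fraction = 0.02))
      ),
      svc = list(
        kind = "vascular", n_sub = 3L, volume_fraction = 0.005,
        outflows = list(list(target = "right_heart", fraction = 0.24))
      ),
      right_heart = list(
        kind = "vascular", n_sub = 2L, volume_fraction = 0.036,
        outflows = list(list(target = "lung", fraction = 1))
      ),
      lung = list(
        kind = "organ", volume_fraction = 0.09,
        ps_ml_s = 1, ecv_ml_per_kg = 7,
        outflows = list(list(target = "left_heart", fraction = 1))
      ),
      left_heart = list(
        kind = "vascular", n_sub = 2L, volume_fraction = 0.036,
        outflows = list(list(target = "aorta", fraction = 1))
      ),
      aorta = list(
        kind = "vascular", n_sub = 4L, volume_fraction = 0.020,
        outflows = list(
          list(target = "cerebral_artery", fraction = 0.12),
          list(target = "coronary", fraction = 0.04),
          list(target = "upper_extremities", fraction = 0.06),
          list(target = "gi", fraction = 0.15),
          list(target = "spleen", fraction = 0.03),
          list(target = "liver", fraction = 0.065),
          list(target = "kidneys", fraction = 0.19),
          list(target = "lower_body", fraction = 0.325),
          list(target = "peripheral_vein", fraction = 0.02,
               recirculation = TRUE)
        )
      ),
      cerebral_artery = list(
        kind = "vascular", n_sub = 5L, volume_fraction = 0.004,
        outflows = list(list(target = "brain", fraction = 0.12))
      ),
      # intact blood-brain barrier: no vascular-extracellular exchange
      brain = list(
        kind = "organ", volume_fraction = 0.025,
        ps_ml_s = 0, ecv_ml_per_kg = 0,
        outflows = list(list(target = "cerebral_vein", fraction = 0.12))
      ),
      cerebral_vein = list(
        kind = "vascular", n_sub = 2L, volume_fraction = 0.005,
        outflows = list(list(target = "svc", fraction = 0.12,
                             recirculation = TRUE))
      ),
      coronary = list(
        kind = "organ", volume_fraction = 0.012,
        ps_ml_s = 0.5, ecv_ml_per_kg = 4,
        outflows = list(list(target = "svc", fraction = 0.04,
                             recirculation = TRUE))
      ),
      upper_extremities = list(
        kind = "organ", volume_fraction = 0.06,
        ps_ml_s = 2, ecv_ml_per_kg = 40,
        outflows = list(list(target = "svc", fraction = 0.06,
                             recirculation = TRUE))
      ),
      gi = list(
        kind = "organ", volume_fraction = 0.08,
        ps_ml_s = 4, ecv_ml_per_kg = 15,
        outflows = list(list(target = "portal_vein", fraction = 0.15))
      ),
      spleen = list(
        kind = "organ", volume_fraction = 0.015,
        ps_ml_s = 1, ecv_ml_per_kg = 3,
        outflows = list(list(target = "portal_vein", fraction = 0.03))
      ),
      portal_vein = list(
        kind = "vascular", n_sub = 2L, volume_fraction = 0.008,
        outflows = list(list(target = "liver", fraction = 0.18))
      ),
      liver = list(
        kind = "organ", volume_fraction = 0.11,
        ps_ml_s = 6, ecv_ml_per_kg = 12,
        outflows = list(list(target = "ivc", fraction = 0.245))
      ),
      kidneys = list(
        kind = "organ", volume_fraction = 0.025,
        ps_ml_s = 5, ecv_ml_per_kg = 8,
        outflows = list(list(target = "ivc", fraction = 0.19))
      ),
      lower_body = list(
        kind = "organ", volume_fraction = 0.442,
        ps_ml_s = 8, ecv_ml_per_kg = 120,
        outflows = list(list(target = "ivc", fraction = 0.325))
      ),
      ivc = list(
        kind = "vascular", n_sub = 2L, volume_fraction = 0.025,
        outflows = list(list(target = "right_heart", fraction = 0.76,
                             recirculation = TRUE))
      )
    ),
    calibration = list(
      hu_per_mg_ml = list(`80` = 40, `120` = 25),
      baseline_hu = 50
    )
  )
}

#' Read or write a model configuration as YAML
#'
#' `write_config()` serialises a configuration list to YAML with a short
#' header flagging that the physiological fractions are reference-man
#' assumptions; `read_config()` loads it back and validates it.
#'
#' @param config configuration list as returned by [default_config()].
#' @param path file path of the YAML configuration.
#' @return `read_config()` returns the validated configuration list;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  header <- c(
    "# pbpkct model configuration",
    "# Organ flow/volume fractions, PS values and the HU calibration are",
    "# reference-man assumptions, not fitted to any individual patient.",
    ""
  )
  writeLines(c(header, yaml::as.yaml(config)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  config <- yaml::read_yaml(path)
  # YAML reads n_sub as plain integers/doubles; coerce where present
  config$compartments <- lapply(config$compartments, function(cp) {
    if (!is.null(cp$n_sub)) cp$n_sub <- as.integer(cp$n_sub)
    cp
  })
  validate_config(config)
  config
}

#' Validate a model configuration
#'
#' Checks structural consistency: every outflow edge targets a known
#' compartment, blood-volume fractions sum to 1 (within 1e-6), and blood
#' flow is conserved at every compartment (inflow fractions equal outflow
#' fractions within 1e-9 relative, counting recirculation edges as part of
#' the physiological loop).
#'
#' @param config configuration list.
#' @return The configuration, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  comps <- config$compartments
  if (is.null(comps) || length(comps) == 0L)
    stop("configuration error: no compartments defined", call. = FALSE)
  nm <- names(comps)
  if (any(nm == "") || anyDuplicated(nm))
    stop("configuration error: compartments must have unique names",
         call. = FALSE)

  for (cn in nm) {
    for (e in comps[[cn]]$outflows) {
      if (!(e$target %in% nm))
        stop(sprintf(
          "configuration error: unknown compartment name '%s' (outflow of '%s')",
          e$target, cn), call. = FALSE)
      if (!is.numeric(e$fraction) || e$fraction <= 0)
        stop(sprintf("configuration error: non-positive flow fraction on %s -> %s",
                     cn, e$target), call. = FALSE)
    }
  }

  vf <- vapply(comps, function(cp) cp$volume_fraction, numeric(1))
  if (any(vf <= 0))
    stop("configuration error: volume fractions must be strictly positive",
         call. = FALSE)
  if (abs(sum(vf) - 1) > 1e-6)
    stop(sprintf(
      "configuration error: blood volume fractions not summing to 1 (sum = %.8f)",
      sum(vf)), call. = FALSE)

  flow_in <- flow_out <- stats::setNames(numeric(length(nm)), nm)
  for (cn in nm) {
    for (e in comps[[cn]]$outflows) {
      flow_out[[cn]] <- flow_out[[cn]] + e$fraction
      flow_in[[e$target]] <- flow_in[[e$target]] + e$fraction
    }
  }
  bad <- nm[abs(flow_in - flow_out) > 1e-9 * pmax(flow_in, flow_out, 1e-12)]
  if (length(bad))
    stop(sprintf(
      "configuration error: unbalanced flows at compartment(s): %s (in = %s, out = %s)",
      paste(bad, collapse = ", "),
      paste(signif(flow_in[bad], 10), collapse = ", "),
      paste(signif(flow_out[bad], 10), collapse = ", ")), call. = FALSE)

  if (!is.null(config$injection_site) &&
      !(config$injection_site %in% nm))
    stop("configuration error: unknown compartment name for injection_site",
         call. = FALSE)
  for (tap in config$output_taps)
    if (!(tap %in% nm))
      stop(sprintf("configuration error: unknown compartment name '%s' in output_taps",
                   tap), call. = FALSE)
  invisible(config)
}
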