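#' Time-density curve
#'
#' Container for a CT attenuation curve at a region of interest:
#' attenuation (HU) over a strictly increasing time grid, together with a
#' label (arterial / venous / simulated) and, when known, the unenhanced
#' baseline attenuation.
#'
#' @param time sample times, s; strictly increasing, at least 3 samples.
#' @param attenuation attenuations, HU; finite, same length as `time`.
#' @param label one of `"arterial"`, `"venous"`, `"simulated"`.
#' @param baseline unenhanced background attenuation in HU, or `NA` if it
#'   is to be estimated from the pre-arrival samples.
#' @return An object of class `tdc`.
#' @export
#' @examples
#' tdc(0:10, c(50, 50, 60, 120, 300, 420, 380, 300, 220, 160, 120))
tdc <- function(time, attenuation,
                label = c("arterial", "venous", "simulated"),
                baseline = NA_real_) {
  label <- match.arg(label)
  time <- as.numeric(time); attenuation <- as.numeric(attenuation)
  if (length(time) < 3L)
    stop("a TDC needs at least 3 samples", call. = FALSE)
  if (length(attenuation) != length(time))
    stop("time and attenuation lengths differ", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (any(!is.finite(attenuation)))
    stop("attenuation must be finite", call. = FALSE)
  structure(list(time = time, attenuation = attenuation, label = label,
                 baseline = as.numeric(baseline)),
            class = "tdc")
}

#' @export
print.tdc <- function(x, ...) {
  cat(sprintf(
    "<tdc:%s> %d samples, %g-%g s, peak %.1f HU%s\n", x$label,
    length(x$time), min(x$time), max(x$time), max(x$attenuation),
    if (is.na(x$baseline)) "" else sprintf(", baseline %g HU", x$baseline)))
  invisible(x)
}

#' @export
plot.tdc <- function(x, ...) {
  graphics::plot(x$time, x$attenuation, type = "l",
                 xlab = "time (s)", ylab = "attenuation (HU)",
                 main = paste("TDC:", x$label), ...)
  if (!is.na(x$baseline))
    graphics::abline(h = x$baseline, lty = 3)
  invisible(x)
}

#' Extract the clinical metrics of a time-density curve
#'
#' Peak attenuation is the curve maximum; time to peak (TTP) is the time
#' of the first sample attaining it (first-maximum tie-break); maximum
#' enhancement (ME) is peak attenuation minus the baseline. If no
#' baseline is supplied, it is estimated as the mean of the pre-arrival
#' samples in the first 5 s of the curve (the scan-delay convention); an
#' explicit baseline always overrides. No sub-sample peak interpolation
#' is performed unless `refine_peak = TRUE`, which applies a parabolic
#' three-point refinement of the peak position.
#'
#' @param curve a [tdc()].
#' @param baseline background attenuation in HU, `"auto"` (default: use
#'   the curve's stored baseline if set, otherwise the pre-arrival mean).
#' @param refine_peak logical; parabolic sub-sample refinement of the peak.
#' @return An object of class `tdc_metrics`: `me` (HU), `ttp` (s),
#'   `peak_attenuation` (HU), `baseline_used` (HU), `mtt` (s, `NA` unless
#'   set by [compute_mtt()]).
#' @export
#' @examples
#' curve <- tdc(0:10, c(50, 50, 60, 120, 300, 558.6, 380, 300, 220, 160, 120))
#' extract_metrics(curve, baseline = 50)
extract_metrics <- function(curve, baseline = "auto", refine_peak = FALSE) {
  stopifnot(inherits(curve, "tdc"))
  att <- curve$attenuation; tt <- curve$time
  if (identical(baseline, "auto")) {
    if (!is.na(curve$baseline)) {
      b <- curve$baseline
    } else {
      pre <- att[tt <= tt[1L] + 5]
      if (diff(range(att)) < .Machine$double.eps^0.5)
        stop("degenerate curve: flat attenuation, cannot auto-estimate baseline",
             call. = FALSE)
      b <- mean(pre)
    }
  } else {
    b <- as.numeric(baseline)
    if (!is.finite(b)) stop("baseline must be finite", call. = FALSE)
  }
  i_pk <- which.max(att)                     # first maximum wins
  peak <- att[i_pk]; ttp <- tt[i_pk]
  if (refine_peak && i_pk > 1L && i_pk < length(tt)) {
    y <- att[(i_pk - 1L):(i_pk + 1L)]
    denom <- y[1L] - 2 * y[2L] + y[3L]
    if (denom < 0) {
      delta <- 0.5 * (y[1L] - y[3L]) / denom
      h <- mean(diff(tt[(i_pk - 1L):(i_pk + 1L)]))
      ttp <- ttp + delta * h
      peak <- y[2L] - 0.25 * (y[1L] - y[3L]) * delta
    }
  }
  if (b > peak)
    warning(sprintf(
      "baseline (%.1f HU) exceeds peak attenuation (%.1f HU); ME is negative",
      b, peak))
  structure(list(me = peak - b, ttp = ttp, peak_attenuation = peak,
                 baseline_used = b, mtt = NA_real_, label = curve$label),
            class = "tdc_metrics")
}

#' @export
print.tdc_metrics <- function(x, ...) {
  cat(sprintf("<tdc_metrics:%s> ME %.1f HU (peak %.1f - baseline %.1f), TTP %.1f s%s\n",
              x$label, x$me, x$peak_attenuation, x$baseline_used, x$ttp,
              if (is.na(x$mtt)) "" else sprintf(", MTT %.1f s", x$mtt)))
  invisible(x)
}

#' Mean transit time from arterial and venous peak times
#'
#' The operational definition used with intracranial TDCs: venous peak
#' time minus arterial peak time. A negative value (venous peaking before
#' arterial) is physiologically implausible and is returned with a
#' warning rather than an error.
#'
#' @param arterial_ttp arterial time to peak, s (non-negative).
#' @param venous_ttp venous time to peak, s (non-negative).
#' @return Mean transit time in s.
#' @export
#' @examples
#' compute_mtt(21, 28)  # 7 s
compute_mtt <- function(arterial_ttp, venous_ttp) {
  if (any(c(arterial_ttp, venous_ttp) < 0))
    stop("peak times must be non-negative", call. = FALSE)
  mtt <- venous_ttp - arterial_ttp
  if (any(mtt < 0))
    warning("venous peak precedes arterial peak; MTT is negative")
  mtt
}

#' Read and write time-density curves as CSV
#'
#' Plain two-column CSV (`time_s`, `hu`) with optional `# key: value`
#' metadata lines (`label`, `baseline`) before the header. Values are
#' written at full double precision so a write/read round trip is
#' lossless. Decimal points must be periods; a comma-decimal dialect is
#' rejected with an explicit message.
#'
#' @param path file path.
#' @param curve a [tdc()].
#' @return `read_tdc_csv()` returns a [tdc()]; `write_tdc_csv()` returns
#'   `path` invisibly.
#' @export
read_tdc_csv <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^\\s*#", lines)
  meta <- list()
  for (ln in lines[meta_idx]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- trimws(m[3L])
  }
  body <- if (length(meta_idx)) lines[-meta_idx] else lines
  if (!length(body) || !grepl("time_s", body[1L]) || !grepl("hu", body[1L]))
    stop(sprintf("parse error in %s: expected header 'time_s,hu' (line %d)",
                 path, if (length(meta_idx)) max(meta_idx) + 1L else 1L),
         call. = FALSE)
  if (grepl(";", body[1L], fixed = TRUE))
    stop(sprintf(
      "parse error in %s: semicolon-separated (comma decimal mark) dialect detected; this reader requires the period-decimal CSV dialect",
      path), call. = FALSE)
  n_cols <- length(strsplit(body[1L], ",", fixed = TRUE)[[1L]])
  n_fields <- lengths(strsplit(body[-1L], ",", fixed = TRUE))
  if (any(n_fields > n_cols))
    stop(sprintf(
      "parse error in %s: data line %d has %d fields for %d columns; values appear to use a comma decimal mark, but this reader requires the period-decimal CSV dialect",
      path, which(n_fields > n_cols)[1L] + 1L,
      max(n_fields), n_cols), call. = FALSE)
  df <- utils::read.csv(text = body, colClasses = "character")
  for (col in c("time_s", "hu"))
    if (!col %in% names(df))
      stop(sprintf("parse error in %s: missing column '%s'", path, col),
           call. = FALSE)
  time <- suppressWarnings(as.numeric(df$time_s))
  hu <- suppressWarnings(as.numeric(df$hu))
  if (any(is.na(time)) || any(is.na(hu)))
    stop(sprintf("parse error in %s: non-numeric value at data line %d",
                 path, which(is.na(time) | is.na(hu))[1L]), call. = FALSE)
  bad <- which(diff(time) <= 0)
  if (length(bad)) {
    offset <- length(meta_idx) + 1L  # metadata lines + header precede data
    stop(sprintf("parse error in %s: time not strictly increasing at line %d",
                 path, bad[1L] + 1L + offset), call. = FALSE)
  }
  tdc(time, hu,
      label = meta$label %||% "arterial",
      baseline = as.numeric(meta$baseline %||% NA))
}

#' @rdname read_tdc_csv
#' @export
write_tdc_csv <- function(curve, path) {
  stopifnot(inherits(curve, "tdc"))
  lines <- c(
    sprintf("# label: %s", curve$label),
    if (!is.na(curve$baseline)) sprintf("# baseline: %.17g", curve$baseline),
    "time_s,hu",
    sprintf("%.17g,%.17g", curve$time, curve$attenuation))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate one patient's intracranial time-density curve
#'
#' Convenience chain: body parameters, compartment model, ODE
#' integration, and conversion to HU at the protocol's tube voltage.
#'
#' @param profile a [patient_profile()].
#' @param protocol an [injection_protocol()].
#' @param config model configuration.
#' @param calib an [enhancement_calibration()].
#' @param recirculation passed to [build_model()].
#' @param ... passed to [simulate_contrast()].
#' @return A [tdc()] labelled `"simulated"`.
#' @export
#' @examples
#' curve <- simulate_patient_tdc(patient_profile("male", 170, 75))
#' extract_metrics(curve)
simulate_patient_tdc <- function(profile, protocol = injection_protocol(),
                                 config = default_config(),
                                 calib = enhancement_calibration(
                                   config$calibration$hu_per_mg_ml,
                                   config$calibration$baseline_hu),
                                 recirculation = FALSE, ...) {
  body <- compute_body_parameters(profile, config)
  model <- build_model(body, config, recirculation = recirculation)
  curve <- simulate_contrast(model, protocol, ...)
  concentration_to_hu(curve, calib, kv = protocol$tube_voltage)
}
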