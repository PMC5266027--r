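#' Synthetic cohort specification
#'
#' Describes a study cohort to emulate: per-sex counts and anthropometry,
#' whether the group is healthy control or infarct, the infarct effect
#' (multiplicative attenuation of maximum enhancement, and a mean
#' transit-time prolongation, an abstraction of reduced anterior cerebral
#' flow), and the measurement-noise layer (HU noise on enhancement, jitter
#' on peak times).
#'
#' Defaults mirror the study structure this pipeline emulates: 44 controls
#' split 19 male / 25 female, or 57 infarct patients split 46 / 11; adult
#' anthropometry male 170 +/- 6 cm, 70 +/- 10 kg and female 160 +/- 6 cm,
#' 60 +/- 10 kg; HU noise sd 30, peak-time jitter sd 1.5 s.
#'
#' @param n_male,n_female patient counts per sex (non-negative).
#' @param group `"control"` or `"infarct"`.
#' @param me_factor multiplicative ME attenuation in (0, 1]; 1 for
#'   controls.
#' @param mtt_prolongation_s additive venous-arterial peak-gap increase, s.
#' @param height_mean,height_sd,weight_mean,weight_sd per-sex normal
#'   anthropometry parameters (named vectors `c(male = , female = )` for
#'   the means).
#' @param noise_hu sd of Gaussian HU measurement noise.
#' @param ttp_jitter_s sd of Gaussian peak-time jitter, s.
#' @param mtt_base_s mean healthy venous-arterial peak gap, s.
#' @param seed integer RNG seed; makes generation fully deterministic.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec(19, 25, seed = 7)
cohort_spec <- function(n_male, n_female,
                        group = c("control", "infarct"),
                        me_factor = if (match.arg(group) == "control") 1 else 0.8,
                        mtt_prolongation_s =
                          if (match.arg(group) == "control") 0 else 2,
                        height_mean = c(male = 170, female = 160),
                        height_sd = 6,
                        weight_mean = c(male = 70, female = 60),
                        weight_sd = 10,
                        noise_hu = 30, ttp_jitter_s = 1.5,
                        mtt_base_s = 7,
                        seed = 1L) {
  group <- match.arg(group)
  if (n_male < 0 || n_female < 0)
    stop("cohort counts must be non-negative", call. = FALSE)
  if (n_male + n_female == 0)
    stop("empty cohort: at least one patient required", call. = FALSE)
  if (me_factor <= 0 || me_factor > 1)
    stop("me_factor must lie in (0, 1]", call. = FALSE)
  if (noise_hu < 0 || ttp_jitter_s < 0 || height_sd < 0 || weight_sd < 0)
    stop("standard deviations must be non-negative", call. = FALSE)
  structure(list(
    n_male = as.integer(n_male), n_female = as.integer(n_female),
    group = group, me_factor = me_factor,
    mtt_prolongation_s = mtt_prolongation_s,
    height_mean = height_mean, height_sd = height_sd,
    weight_mean = weight_mean, weight_sd = weight_sd,
    noise_hu = noise_hu, ttp_jitter_s = ttp_jitter_s,
    mtt_base_s = mtt_base_s, seed = as.integer(seed)
  ), class = "cohort_spec")
}

# run code under a seed without disturbing the caller's RNG stream
local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit(
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env))
  set.seed(seed)
  force(code)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

#' Generate a synthetic cohort with simulated and "measured" curves
#'
#' Draws per-sex anthropometry, runs the whole-body simulator for each
#' patient, and emulates a measured acquisition: the measured curve is the
#' patient's simulated curve with its enhancement scaled by the infarct ME
#' factor, shifted by the patient's peak-time jitter, and overlaid with
#' pointwise Gaussian HU noise. The recorded measured metrics apply the
#' same effect and noise at the metric level (one peak-reading error per
#' patient), the way a clinical peak value is read off a curve, so that
#' with zero noise and unit effect measured and simulated metrics agree
#' exactly. Measured MTT is drawn around the healthy venous-arterial peak
#' gap plus any infarct prolongation (the simulator itself has no venous
#' intracranial tap).
#'
#' Fully deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param protocol an [injection_protocol()].
#' @param config model configuration.
#' @param dt_out output grid step for the per-patient simulations, s.
#' @return An object of class `cohort`: list of per-patient records, each
#'   with `profile`, `sim_metrics`, `meas_metrics`, `sim_tdc`, `meas_tdc`
#'   (or `error` when a simulation failed), plus the `spec`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(2, 2, seed = 7), dt_out = 0.5)
#' length(coh$patients)
generate_cohort <- function(spec, protocol = injection_protocol(),
                            config = default_config(), dt_out = 0.1) {
  stopifnot(inherits(spec, "cohort_spec"))
  calib <- enhancement_calibration(config$calibration$hu_per_mg_ml,
                                   config$calibration$baseline_hu)
  local_seed(spec$seed, {
    sexes <- c(rep("male", spec$n_male), rep("female", spec$n_female))
    n <- length(sexes)
    heights <- weights <- numeric(n)
    for (i in seq_len(n)) {
      s <- sexes[i]
      heights[i] <- rnorm_trunc(1, spec$height_mean[[s]], spec$height_sd,
                                100, 230)
      weights[i] <- rnorm_trunc(1, spec$weight_mean[[s]], spec$weight_sd,
                                25, 250)
    }
    me_noise <- stats::rnorm(n, 0, spec$noise_hu)
    ttp_jitter <- stats::rnorm(n, 0, spec$ttp_jitter_s)
    mtt_meas <- stats::rnorm(n, spec$mtt_base_s + spec$mtt_prolongation_s,
                             spec$ttp_jitter_s)

    patients <- vector("list", n)
    for (i in seq_len(n)) {
      prof <- patient_profile(sexes[i], heights[i], weights[i],
                              id = sprintf("%s-%03d", spec$group, i))
      rec <- tryCatch({
        sim <- simulate_patient_tdc(prof, protocol, config, calib,
                                    dt_out = dt_out)
        sim_m <- extract_metrics(sim)
        enh <- sim$attenuation - calib$baseline_hu
        enh_shift <- stats::approx(sim$time + ttp_jitter[i], enh,
                                   xout = sim$time, rule = 2)$y
        curve_noise <- if (spec$noise_hu > 0)
          stats::rnorm(length(sim$time), 0, spec$noise_hu) else 0
        meas <- tdc(sim$time,
                    calib$baseline_hu + spec$me_factor * enh_shift +
                      curve_noise,
                    label = "arterial", baseline = calib$baseline_hu)
        meas_m <- structure(list(
          me = spec$me_factor * sim_m$me + me_noise[i],
          ttp = sim_m$ttp + ttp_jitter[i],
          peak_attenuation = spec$me_factor * sim_m$me + me_noise[i] +
            calib$baseline_hu,
          baseline_used = calib$baseline_hu,
          mtt = mtt_meas[i], label = "arterial"), class = "tdc_metrics")
        list(profile = prof, sim_metrics = sim_m, meas_metrics = meas_m,
             sim_tdc = sim, meas_tdc = meas, error = NULL)
      }, error = function(e)
        list(profile = prof, sim_metrics = NULL, meas_metrics = NULL,
             sim_tdc = NULL, meas_tdc = NULL, error = conditionMessage(e)))
      patients[[i]] <- rec
    }
    structure(list(patients = patients, spec = spec, protocol = protocol),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  ok <- sum(vapply(x$patients, function(p) is.null(p$error), logical(1)))
  cat(sprintf("<cohort:%s> %d male + %d female (%d simulated ok), seed %d\n",
              x$spec$group, x$spec$n_male, x$spec$n_female, ok,
              x$spec$seed))
  invisible(x)
}

new_comparison <- function(metric, stratum, x, y, t, df, p, paired,
                           alpha = 0.05, degenerate = FALSE) {
  structure(list(
    metric = metric, stratum = stratum,
    mean_a = mean(x), mean_b = mean(y),
    sd_a = stats::sd(x), sd_b = stats::sd(y),
    n_a = length(x), n_b = length(y),
    t_statistic = t, degrees_of_freedom = df, p_value = p,
    paired = paired, significant = is.finite(p) && p < alpha,
    degenerate = degenerate
  ), class = "comparison_result")
}

#' Paired t-test of two metric vectors
#'
#' Classical two-sided paired t-test on the differences `x - y` with
#' `n - 1` degrees of freedom. Degenerate inputs get explicit sentinels:
#' identical vectors give `t = 0, p = 1`; nonzero differences of exactly
#' zero variance give an infinite-t sentinel with `p = 0` and the
#' `degenerate` flag set.
#'
#' @param x,y equal-length numeric vectors (actual and simulated values),
#'   length at least 2.
#' @param alpha significance level used for the `significant` flag.
#' @param metric,stratum labels carried into the result.
#' @return A `comparison_result`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
paired_t <- function(x, y, alpha = 0.05, metric = NA_character_,
                     stratum = "all") {
  if (length(x) != length(y))
    stop("paired_t: length mismatch between x and y", call. = FALSE)
  if (length(x) < 2L)
    stop("paired_t: need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(new_comparison(metric, stratum, x, y, 0, length(d) - 1L, 1,
                            TRUE, alpha))
    return(new_comparison(metric, stratum, x, y, sign(mean(d)) * Inf,
                          length(d) - 1L, 0, TRUE, alpha,
                          degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  new_comparison(metric, stratum, x, y,
                 unname(tt$statistic), unname(tt$parameter),
                 tt$p.value, TRUE, alpha)
}

#' Two-sample t-test of two groups
#'
#' Unpaired comparison; Welch's unequal-variance form by default, pooled
#' variance with `var_equal = TRUE`. Zero-variance degenerate cases are
#' handled with the same sentinels as [paired_t()].
#'
#' @param x,y numeric vectors, each of length at least 2.
#' @param var_equal pooled-variance (classical) form instead of Welch.
#' @inheritParams paired_t
#' @return A `comparison_result`.
#' @export
two_sample_t <- function(x, y, var_equal = FALSE, alpha = 0.05,
                         metric = NA_character_, stratum = "all") {
  if (length(x) < 2L || length(y) < 2L)
    stop("two_sample_t: need at least 2 observations per group",
         call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(new_comparison(metric, stratum, x, y, 0,
                            length(x) + length(y) - 2L, 1, FALSE, alpha))
    return(new_comparison(metric, stratum, x, y,
                          sign(mean(x) - mean(y)) * Inf,
                          length(x) + length(y) - 2L, 0, FALSE, alpha,
                          degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  new_comparison(metric, stratum, x, y, unname(tt$statistic),
                 unname(tt$parameter), tt$p.value, FALSE, alpha)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<%s t> %s [%s]: %.2f vs %.2f, t = %.3f (df %.1f), p = %.4g%s\n",
    if (x$paired) "paired" else "two-sample",
    x$metric %||% "metric", x$stratum, x$mean_a, x$mean_b,
    x$t_statistic, x$degrees_of_freedom, x$p_value,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Chi-square test of sex-ratio balance between two groups
#'
#' @param males_a,females_a,males_b,females_b counts per group.
#' @return The `htest` from [stats::chisq.test()] on the 2x2 table.
#' @export
#' @examples
#' sex_balance_test(19, 25, 46, 11)$p.value
sex_balance_test <- function(males_a, females_a, males_b, females_b) {
  stats::chisq.test(matrix(c(males_a, females_a, males_b, females_b),
                           nrow = 2, byrow = TRUE))
}

#' Actual-versus-simulated validation of a cohort
#'
#' Reproduces the paired validation workflow on a generated cohort:
#' per-patient measured and simulated ME and TTP, paired t-tests overall
#' and stratified by sex, and mean absolute percent differences. Patients
#' whose simulation failed are excluded and counted.
#'
#' @param cohort a [generate_cohort()] result.
#' @param alpha significance level.
#' @return An object of class `validation_report`: `table` (per-patient
#'   data frame), `comparisons` (list of `comparison_result`),
#'   `pct_diff` (mean absolute percent differences for ME and TTP),
#'   `n_excluded`, `spec`.
#' @export
run_validation <- function(cohort, alpha = 0.05) {
  stopifnot(inherits(cohort, "cohort"))
  ok <- vapply(cohort$patients, function(p) is.null(p$error), logical(1))
  n_excluded <- sum(!ok)
  pats <- cohort$patients[ok]
  if (!length(pats))
    stop("empty cohort: no patient simulated successfully", call. = FALSE)
  tab <- do.call(rbind, lapply(pats, function(p) data.frame(
    id = p$profile$id, sex = p$profile$sex,
    height_cm = p$profile$height, weight_kg = p$profile$weight,
    me_actual = p$meas_metrics$me, me_simulated = p$sim_metrics$me,
    ttp_actual = p$meas_metrics$ttp, ttp_simulated = p$sim_metrics$ttp,
    mtt_actual = p$meas_metrics$mtt,
    stringsAsFactors = FALSE)))

  strata <- list(all = rep(TRUE, nrow(tab)),
                 male = tab$sex == "male",
                 female = tab$sex == "female")
  comparisons <- list()
  for (metric in c("ME", "TTP")) {
    a <- tab[[if (metric == "ME") "me_actual" else "ttp_actual"]]
    s <- tab[[if (metric == "ME") "me_simulated" else "ttp_simulated"]]
    for (st in names(strata)) {
      keep <- strata[[st]]
      comparisons[[paste(metric, st, sep = ".")]] <-
        if (sum(keep) >= 2L)
          paired_t(a[keep], s[keep], alpha, metric, st)
        else structure(list(metric = metric, stratum = st,
                            mean_a = if (any(keep)) mean(a[keep]) else NA_real_,
                            mean_b = if (any(keep)) mean(s[keep]) else NA_real_,
                            sd_a = NA_real_, sd_b = NA_real_,
                            n_a = sum(keep), n_b = sum(keep),
                            t_statistic = NA_real_,
                            degrees_of_freedom = 0,
                            p_value = NA_real_, paired = TRUE,
                            significant = NA, degenerate = TRUE,
                            note = "not computable (fewer than 2 pairs)"),
                       class = "comparison_result")
    }
  }
  pct <- function(a, s) mean(abs(a - s) / pmax(abs(s), .Machine$double.eps)) * 100
  structure(list(
    table = tab,
    comparisons = comparisons,
    pct_diff = c(ME = pct(tab$me_actual, tab$me_simulated),
                 TTP = pct(tab$ttp_actual, tab$ttp_simulated)),
    n_excluded = n_excluded,
    alpha = alpha,
    spec = cohort$spec
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report: %s cohort, n = %d (%d excluded)\n\n",
              x$spec$group, nrow(x$table), x$n_excluded))
  cat(sprintf("| metric | stratum | n | actual mean | simulated mean | t | df | p | sig |\n"))
  cat("|---|---|---|---|---|---|---|---|---|\n")
  for (cmp in x$comparisons)
    cat(sprintf("| %s | %s | %d | %.2f | %.2f | %s | %.1f | %s | %s |\n",
                cmp$metric, cmp$stratum, cmp$n_a, cmp$mean_a, cmp$mean_b,
                if (is.na(cmp$t_statistic)) "-" else sprintf("%.3f", cmp$t_statistic),
                cmp$degrees_of_freedom,
                if (is.na(cmp$p_value)) "-" else sprintf("%.4g", cmp$p_value),
                if (isTRUE(cmp$significant)) "yes"
                else if (isFALSE(cmp$significant)) "no" else "-"))
  cat(sprintf("\nMean absolute percent difference: ME %.2f%%, TTP %.2f%%\n",
              x$pct_diff[["ME"]], x$pct_diff[["TTP"]]))
  invisible(x)
}

#' Serialise a validation report to JSON
#'
#' Deterministic (byte-identical for identical reports) JSON rendering of
#' the per-patient table, comparisons and summary figures.
#'
#' @param report a [run_validation()] result.
#' @param path optional file to write to.
#' @return JSON string (invisibly when `path` is given).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  payload <- list(
    group = report$spec$group,
    seed = report$spec$seed,
    n = nrow(report$table),
    n_excluded = report$n_excluded,
    pct_diff = as.list(report$pct_diff),
    comparisons = lapply(report$comparisons, function(cmp)
      cmp[c("metric", "stratum", "n_a", "mean_a", "mean_b", "sd_a",
            "sd_b", "t_statistic", "degrees_of_freedom", "p_value",
            "paired", "significant")]),
    patients = report$table)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Monte-Carlo calibration of the paired test on the noise layer
#'
#' Replicates the cohort noise layer many times over a fixed vector of
#' simulated maximum enhancements and reports how often the paired t-test
#' rejects. With `me_factor = 1` the differences are pure noise and the
#' rejection rate estimates the type-I error; with `me_factor < 1` it
#' estimates power against that attenuation.
#'
#' @param sim_me vector of simulated ME values (HU), one per patient.
#' @param n_replicates number of Monte-Carlo replicates.
#' @param noise_hu sd of the per-patient ME measurement noise, HU.
#' @param me_factor multiplicative ME effect applied to the "actual" arm.
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return Rejection rate (fraction of replicates with p < alpha).
#' @export
#' @examples
#' replicate_paired_tests(rep(400, 44), 200, noise_hu = 30, seed = 1)
replicate_paired_tests <- function(sim_me, n_replicates, noise_hu = 30,
                                   me_factor = 1, alpha = 0.05,
                                   seed = 1L) {
  stopifnot(length(sim_me) >= 2L, n_replicates >= 1L)
  local_seed(seed, {
    rejected <- logical(n_replicates)
    for (r in seq_len(n_replicates)) {
      actual <- me_factor * sim_me + stats::rnorm(length(sim_me), 0, noise_hu)
      rejected[r] <- paired_t(actual, sim_me, alpha)$p_value < alpha
    }
    mean(rejected)
  })
}
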