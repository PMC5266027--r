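#' Bolus injection protocol
#'
#' Defines the contrast bolus and scan window. Defaults are the standard
#' cranial CT perfusion protocol: 45 mL of 370 mg I/mL contrast at 4 mL/s,
#' scan starting 5 s after injection begins and lasting 50 s, tube voltage
#' 80 kV. Injection duration is `volume / rate` (11.25 s by default).
#'
#' @param volume injected contrast volume, mL.
#' @param rate injection rate, mL/s.
#' @param iodine_concentration iodine concentration of the agent, mg I/mL.
#' @param scan_delay time from injection start to scan start, s.
#' @param scan_duration scan length, s.
#' @param tube_voltage tube voltage, kV.
#' @return An object of class `injection_protocol`.
#' @export
#' @examples
#' injection_protocol()
injection_protocol <- function(volume = 45, rate = 4,
                               iodine_concentration = 370,
                               scan_delay = 5, scan_duration = 50,
                               tube_voltage = 80) {
  for (f in c("rate", "iodine_concentration", "scan_delay",
              "scan_duration", "tube_voltage")) {
    v <- get(f)
    if (length(v) != 1L || !is.numeric(v) || !is.finite(v) || v <= 0)
      stop(sprintf("invalid '%s': must be a single positive number", f),
           call. = FALSE)
  }
  if (length(volume) != 1L || !is.numeric(volume) || volume < 0)
    stop("invalid 'volume': must be a single non-negative number",
         call. = FALSE)
  structure(list(volume = volume, rate = rate,
                 iodine_concentration = iodine_concentration,
                 scan_delay = scan_delay, scan_duration = scan_duration,
                 tube_voltage = tube_voltage),
            class = "injection_protocol")
}

#' @export
print.injection_protocol <- function(x, ...) {
  cat(sprintf(
    "<injection_protocol> %g mL @ %g mL/s of %g mg I/mL (%.2f s bolus); scan %g-%g s; %g kV\n",
    x$volume, x$rate, x$iodine_concentration, x$volume / x$rate,
    x$scan_delay, x$scan_delay + x$scan_duration, x$tube_voltage))
  invisible(x)
}

#' Bolus mass input rate
#'
#' The forcing term of the ODE system: iodine mass delivery rate at the
#' injection site. A rectangular bolus of `rate * iodine_concentration`
#' mg/s for `t` in `[0, volume/rate)` and 0 afterwards, so its time
#' integral is exactly `volume * iodine_concentration` mg.
#'
#' @param protocol an [injection_protocol()].
#' @param t time(s) since injection start, s; must be non-negative.
#' @return Mass input rate(s) in mg/s, vectorised over `t`.
#' @export
#' @examples
#' injection_input(injection_protocol(), 5)   # 1480 mg/s
injection_input <- function(protocol, t) {
  stopifnot(inherits(protocol, "injection_protocol"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("domain error: injection_input requires t >= 0", call. = FALSE)
  t_inj <- protocol$volume / protocol$rate
  ifelse(t < t_inj, protocol$rate * protocol$iodine_concentration, 0)
}

#' Assemble the patient-scaled compartment model
#'
#' Expands the configured circulatory topology into the coefficient matrix
#' of a linear ODE system in compartment iodine amounts (mg). Vascular
#' compartments with transport delay are realised as short series chains of
#' `n_sub` well-mixed sub-compartments (an Erlang transit approximation
#' that keeps the system a plain ODE); organ compartments contribute a
#' vascular and an extracellular state exchanging at rate PS. When
#' `recirculation = FALSE` (the default, matching a first-pass model that
#' neglects venous reflux) every edge flagged as a recirculation return
#' delivers its contrast flux to an absorbing sink state instead of its
#' physiological target, and the remaining contrast pathway must be
#' acyclic.
#'
#' With the default topology the state dimension is 44 when recirculation
#' is enabled and 45 (the 44 plus the sink) in the default first-pass
#' configuration.
#'
#' @param body a [compute_body_parameters()] result.
#' @param config model configuration with the `compartments` topology.
#' @param recirculation logical; route venous returns back into the
#'   circulation (`TRUE`) or into an absorbing sink (`FALSE`, default).
#' @return An object of class `compartment_model` with elements `M` (the
#'   system matrix, 1/s), `states` (data frame of state name, compartment,
#'   volume), `n_states`, `injection_index`, `taps` (named outlet state
#'   indices with volumes), `body`, `recirculation`.
#' @export
#' @examples
#' bp <- compute_body_parameters(patient_profile("male", 170, 75))
#' m <- build_model(bp)
#' m$n_states
build_model <- function(body, config = default_config(),
                        recirculation = FALSE) {
  stopifnot(inherits(body, "body_parameters"))
  validate_config(config)
  comps <- config$compartments
  nm <- names(comps)
  co <- body$cardiac_output

  check_acyclic_first_pass(comps, recirculation)

  # --- expand compartments into scalar states -----------------------------
  st_name <- character(0); st_comp <- character(0); st_vol <- numeric(0)
  first_state <- last_state <- stats::setNames(integer(length(nm)), nm)
  ec_state <- stats::setNames(rep(NA_integer_, length(nm)), nm)
  for (cn in nm) {
    cp <- comps[[cn]]
    vol <- body$regional_blood_volume[[cn]]
    if (identical(cp$kind, "vascular")) {
      k <- max(1L, as.integer(cp$n_sub %||% 1L))
      idx <- length(st_name) + seq_len(k)
      st_name <- c(st_name, if (k == 1L) cn else paste0(cn, ".", seq_len(k)))
      st_comp <- c(st_comp, rep(cn, k))
      st_vol <- c(st_vol, rep(vol / k, k))
      first_state[[cn]] <- idx[1L]; last_state[[cn]] <- idx[k]
    } else if (identical(cp$kind, "organ")) {
      i <- length(st_name) + 1L
      st_name <- c(st_name, paste0(cn, ".vas"), paste0(cn, ".ec"))
      st_comp <- c(st_comp, cn, cn)
      st_vol <- c(st_vol, vol, body$extracellular_volume[[cn]])
      first_state[[cn]] <- i; last_state[[cn]] <- i
      ec_state[[cn]] <- i + 1L
    } else {
      stop(sprintf("construction error: unknown compartment kind '%s' (%s)",
                   cp$kind, cn), call. = FALSE)
    }
  }
  sink_index <- NA_integer_
  if (!recirculation) {
    sink_index <- length(st_name) + 1L
    st_name <- c(st_name, "sink"); st_comp <- c(st_comp, "sink")
    st_vol <- c(st_vol, NA_real_)
  }
  n <- length(st_name)

  # --- system matrix ------------------------------------------------------
  M <- matrix(0, n, n, dimnames = list(st_name, st_name))
  for (cn in nm) {
    cp <- comps[[cn]]
    q_out <- co * sum(vapply(cp$outflows, function(e) e$fraction, numeric(1)))
    if (identical(cp$kind, "vascular")) {
      k <- max(1L, as.integer(cp$n_sub %||% 1L))
      idx <- first_state[[cn]]:last_state[[cn]]
      for (j in seq_len(k - 1L)) {       # intra-chain transfers
        r <- q_out / st_vol[idx[j]]
        M[idx[j], idx[j]] <- M[idx[j], idx[j]] - r
        M[idx[j + 1L], idx[j]] <- M[idx[j + 1L], idx[j]] + r
      }
    }
    out_i <- last_state[[cn]]
    for (e in cp$outflows) {
      r <- co * e$fraction / st_vol[out_i]
      M[out_i, out_i] <- M[out_i, out_i] - r
      dest <- if (!recirculation && isTRUE(e$recirculation))
        sink_index else first_state[[e$target]]
      M[dest, out_i] <- M[dest, out_i] + r
    }
    if (identical(cp$kind, "organ")) {
      ps <- cp$ps_ml_s %||% 0
      vvas <- st_vol[first_state[[cn]]]
      vec <- st_vol[ec_state[[cn]]]
      if (ps > 0 && vec > 0) {
        iv <- first_state[[cn]]; ie <- ec_state[[cn]]
        M[iv, iv] <- M[iv, iv] - ps / vvas
        M[ie, iv] <- M[ie, iv] + ps / vvas
        M[ie, ie] <- M[ie, ie] - ps / vec
        M[iv, ie] <- M[iv, ie] + ps / vec
      }
    }
  }

  taps <- config$output_taps
  tap_index <- stats::setNames(last_state[taps], taps)
  check_tap_reachability(comps, config$injection_site, taps, recirculation)

  structure(list(
    M = M,
    states = data.frame(state = st_name, compartment = st_comp,
                        volume = st_vol, stringsAsFactors = FALSE),
    n_states = n,
    injection_index = first_state[[config$injection_site]],
    taps = tap_index,
    tap_volumes = stats::setNames(st_vol[tap_index], taps),
    sink_index = sink_index,
    body = body,
    recirculation = recirculation
  ), class = "compartment_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cycle check on the non-recirculation contrast pathway (Kahn's algorithm)
check_acyclic_first_pass <- function(comps, recirculation) {
  if (recirculation) return(invisible(TRUE))
  nm <- names(comps)
  indeg <- stats::setNames(numeric(length(nm)), nm)
  edges <- list()
  for (cn in nm) for (e in comps[[cn]]$outflows) {
    if (isTRUE(e$recirculation)) next
    edges[[cn]] <- c(edges[[cn]], e$target)
    indeg[[e$target]] <- indeg[[e$target]] + 1
  }
  queue <- nm[indeg == 0]; seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (w in edges[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1
      if (indeg[[w]] == 0) queue <- c(queue, w)
    }
  }
  if (seen < length(nm))
    stop(sprintf(
      "construction error: cycle present in first-pass pathway while recirculation = FALSE (involving: %s)",
      paste(nm[indeg > 0], collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

check_tap_reachability <- function(comps, origin, taps, recirculation) {
  reach <- origin
  repeat {
    new <- unique(unlist(lapply(reach, function(cn)
      vapply(Filter(function(e) recirculation || !isTRUE(e$recirculation),
                    comps[[cn]]$outflows),
             function(e) e$target, character(1)))))
    grown <- union(reach, new)
    if (length(grown) == length(reach)) break
    reach <- grown
  }
  missing <- setdiff(taps, reach)
  if (length(missing))
    stop(sprintf(
      "construction error: output tap(s) not reachable from injection site: %s",
      paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.compartment_model <- function(x, ...) {
  cat(sprintf(
    "<compartment_model> %d ODE states (%d compartments%s), recirculation %s\n  taps: %s\n",
    x$n_states, length(unique(x$states$compartment)) -
      as.integer(!is.na(x$sink_index)),
    if (is.na(x$sink_index)) "" else " + sink",
    if (x$recirculation) "on" else "off",
    paste(names(x$taps), collapse = ", ")))
  invisible(x)
}

#' Simulate the contrast concentration curve
#'
#' Integrates the compartment system under the bolus forcing with an
#' adaptive stiff/non-stiff solver (`deSolve::lsoda`) and reports iodine
#' concentration at each output tap on a uniform time grid. The
#' integration is split exactly at the injection end so the rectangular
#' forcing never straddles a solver step. Time zero is injection start;
#' the scan delay only selects which window of the curve is scanned and
#' does not affect the dynamics.
#'
#' @param model a [build_model()] result.
#' @param protocol an [injection_protocol()].
#' @param t_end simulation end time, s; must cover the scan window.
#' @param dt_out output grid step, s.
#' @param rtol,atol solver relative/absolute tolerances.
#' @return An object of class `concentration_curve`: `time` (s),
#'   `concentration` (matrix, mg I/mL, one column per tap),
#'   `injected_mass_cumulative` (mg), `amounts` (matrix of all state
#'   amounts, mg), plus the model and protocol.
#' @export
#' @examples
#' bp <- compute_body_parameters(patient_profile("male", 170, 75))
#' curve <- simulate_contrast(build_model(bp), injection_protocol())
#' max(curve$concentration[, "cerebral_artery"])
simulate_contrast <- function(model, protocol,
                              t_end = protocol$scan_delay +
                                protocol$scan_duration + 5,
                              dt_out = 0.1, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "compartment_model"),
            inherits(protocol, "injection_protocol"))
  if (dt_out <= 0) stop("dt_out must be > 0", call. = FALSE)
  if (t_end < protocol$scan_delay + protocol$scan_duration)
    stop("t_end must cover the scan window (scan_delay + scan_duration)",
         call. = FALSE)

  t_inj <- protocol$volume / protocol$rate
  if (t_inj > t_end)
    warning(sprintf(
      "injection (%.1f s) outlasts the simulated horizon (%.1f s); curve is truncated",
      t_inj, t_end))
  u <- protocol$rate * protocol$iodine_concentration
  t_out <- seq(0, t_end, by = dt_out)
  n <- model$n_states
  e_inj <- numeric(n); e_inj[model$injection_index] <- 1

  deriv <- function(t, A, p) list(as.vector(p$M %*% A) + p$inflow)
  jac <- function(t, A, p) p$M
  run <- function(A0, times, inflow_rate) {
    if (length(times) < 2L)
      return(matrix(A0, nrow = length(times), ncol = n, byrow = TRUE,
                    dimnames = list(NULL, model$states$state)))
    out <- deSolve::lsoda(
      y = stats::setNames(A0, model$states$state), times = times,
      func = deriv, parms = list(M = model$M, inflow = inflow_rate * e_inj),
      jacfunc = jac, jactype = "fullusr", rtol = rtol, atol = atol)
    d <- diagnostics_ok(out, times)
    out[, -1L, drop = FALSE]
  }

  if (protocol$volume == 0 || t_inj >= t_end) {
    amounts <- run(numeric(n), t_out, if (protocol$volume == 0) 0 else u)
  } else {
    t1 <- c(t_out[t_out < t_inj], t_inj)
    t2 <- c(t_inj, t_out[t_out > t_inj])
    a1 <- run(numeric(n), t1, u)
    a2 <- run(a1[nrow(a1), ], t2, 0)
    keep1 <- seq_len(length(t1) - if (t_inj %in% t_out) 0L else 1L)
    amounts <- rbind(a1[keep1, , drop = FALSE],
                     a2[-1L, , drop = FALSE])
  }
  if (nrow(amounts) != length(t_out))
    stop("integration error: output grid mismatch", call. = FALSE)
  if (any(!is.finite(amounts)))
    stop("integration error: NaN/Inf in state trajectory", call. = FALSE)

  conc <- sapply(seq_along(model$taps), function(j)
    amounts[, model$taps[j]] / model$tap_volumes[j])
  conc <- matrix(conc, ncol = length(model$taps),
                 dimnames = list(NULL, names(model$taps)))
  # floor solver noise; anything genuinely negative is an integration fault
  floor_tol <- -1e-8 * max(conc, 1e-12)
  if (any(conc < floor_tol))
    stop("integration error: negative concentration beyond solver tolerance",
         call. = FALSE)
  conc[conc < 0] <- 0

  structure(list(
    time = t_out,
    concentration = conc,
    injected_mass_cumulative = pmin(t_out, t_inj) * u,
    amounts = amounts,
    model = model,
    protocol = protocol
  ), class = "concentration_curve")
}

diagnostics_ok <- function(out, times) {
  if (nrow(out) < length(times))
    stop(sprintf(
      "integration error: solver stopped early at t = %.3f s (tolerance not met)",
      out[nrow(out), 1L]), call. = FALSE)
  invisible(TRUE)
}

#' Total iodine mass in the system
#'
#' Mass-balance audit: the sum of all compartment amounts (including the
#' sink) at the requested times. For a correct integration this equals the
#' cumulative injected mass to within solver tolerance.
#'
#' @param curve a [simulate_contrast()] result.
#' @param t times at which to report, s; must lie on the output grid.
#' @return Named numeric vector of total mass in mg.
#' @export
total_mass_in_system <- function(curve, t = curve$time) {
  stopifnot(inherits(curve, "concentration_curve"))
  idx <- match_grid(t, curve$time)
  stats::setNames(rowSums(curve$amounts[idx, , drop = FALSE]),
                  format(t, trim = TRUE))
}

match_grid <- function(t, grid) {
  idx <- vapply(t, function(ti) {
    j <- which.min(abs(grid - ti))
    if (abs(grid[j] - ti) > 1e-9 * max(1, abs(ti)))
      stop(sprintf("t = %g is not on the output grid", ti), call. = FALSE)
    j
  }, integer(1))
  idx
}

#' Worst-case relative mass-balance error of a simulation
#'
#' Maximum over all output times (after injection start) of
#' `|total mass - cumulative injected| / cumulative injected`.
#'
#' @param curve a [simulate_contrast()] result.
#' @return A single non-negative number.
#' @export
mass_balance_error <- function(curve) {
  stopifnot(inherits(curve, "concentration_curve"))
  inj <- curve$injected_mass_cumulative
  keep <- inj > 0
  if (!any(keep)) return(0)
  tot <- rowSums(curve$amounts)
  max(abs(tot[keep] - inj[keep]) / inj[keep])
}

#' @export
print.concentration_curve <- function(x, ...) {
  pk <- apply(x$concentration, 2, max)
  cat(sprintf("<concentration_curve> %d samples, 0-%g s (dt %g s)\n",
              length(x$time), max(x$time), x$time[2] - x$time[1]))
  for (tp in colnames(x$concentration))
    cat(sprintf("  %s: peak %.3f mg I/mL at %.1f s\n", tp, pk[[tp]],
                x$time[which.max(x$concentration[, tp])]))
  invisible(x)
}
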