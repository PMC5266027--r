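# Shared fixtures. Heavy simulations are memoised so each is run once per
# test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

reference_adult <- function() patient_profile("male", 170, 75)

reference_model <- function(recirculation = FALSE) {
  key <- paste0("model_", recirculation)
  cached(key, build_model(
    compute_body_parameters(reference_adult()),
    recirculation = recirculation))
}

reference_curve <- function() {
  cached("curve", simulate_contrast(reference_model(), injection_protocol()))
}

reference_tdc <- function() {
  cached("tdc", concentration_to_hu(reference_curve()))
}

# smooth arterial-shaped curve with a known analytic peak (gamma-variate
# bolus shape on a flat baseline)
gamma_variate_tdc <- function(dt = 0.1, t_end = 50, baseline = 50,
                              amplitude = 400, t0 = 8, alpha = 3,
                              beta = 3.5) {
  t <- seq(0, t_end, by = dt)
  s <- pmax(t - t0, 0)
  shape <- (s / (alpha * beta))^alpha * exp(alpha - s / beta)
  tdc(t, baseline + amplitude * shape, baseline = baseline)
}

# two-tank washout: tank1 -> tank2 -> out, rectangular mass input into
# tank1. Used as the closed-form oracle for the integrator.
two_tank_config <- function() {
  cfg <- default_config()
  cfg$injection_site <- "tank1"
  cfg$output_taps <- "tank2"
  cfg$compartments <- list(
    tank1 = list(kind = "vascular", n_sub = 1L, volume_fraction = 0.6,
                 outflows = list(list(target = "tank2", fraction = 1))),
    tank2 = list(kind = "vascular", n_sub = 1L, volume_fraction = 0.4,
                 outflows = list(list(target = "tank1", fraction = 1,
                                      recirculation = TRUE))))
  cfg
}

# closed-form amounts for the two-tank chain under a rectangular input of
# rate u for duration t_inj (derived by solving the linear ODE pair by
# variation of constants)
two_tank_analytic <- function(t, u, t_inj, k1, k2) {
  a1_rise <- function(s) (u / k1) * (1 - exp(-k1 * s))
  a2_rise <- function(s) (u / k2) * (1 - exp(-k2 * s)) -
    u * (exp(-k1 * s) - exp(-k2 * s)) / (k2 - k1)
  a1 <- ifelse(t <= t_inj, a1_rise(t),
               a1_rise(t_inj) * exp(-k1 * (t - t_inj)))
  a2 <- ifelse(t <= t_inj, a2_rise(t), {
    s <- t - t_inj
    a2_rise(t_inj) * exp(-k2 * s) +
      k1 * a1_rise(t_inj) * (exp(-k1 * s) - exp(-k2 * s)) / (k2 - k1)
  })
  cbind(tank1 = a1, tank2 = a2)
}

# rescale the cerebral branch flow by `factor`, compensating through the
# lower body so every node stays balanced
scale_cerebral_flow <- function(cfg, factor) {
  f0 <- 0.12
  f1 <- f0 * factor
  delta <- f1 - f0
  set_edge <- function(cfg, from, to, fraction) {
    for (i in seq_along(cfg$compartments[[from]]$outflows)) {
      if (cfg$compartments[[from]]$outflows[[i]]$target == to)
        cfg$compartments[[from]]$outflows[[i]]$fraction <- fraction
    }
    cfg
  }
  cfg <- set_edge(cfg, "aorta", "cerebral_artery", f1)
  cfg <- set_edge(cfg, "aorta", "lower_body", 0.325 - delta)
  cfg <- set_edge(cfg, "cerebral_artery", "brain", f1)
  cfg <- set_edge(cfg, "brain", "cerebral_vein", f1)
  cfg <- set_edge(cfg, "cerebral_vein", "svc", f1)
  cfg <- set_edge(cfg, "lower_body", "ivc", 0.325 - delta)
  cfg <- set_edge(cfg, "svc", "right_heart", 0.24 + delta)
  cfg <- set_edge(cfg, "ivc", "right_heart", 0.76 - delta)
  cfg
}
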