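test_that("default topology expands to the documented state dimension", {
  # first-pass default: full circulation plus an absorbing sink
  expect_identical(reference_model()$n_states, 45L)
  # with venous recirculation enabled the sink disappears
  expect_identical(reference_model(recirculation = TRUE)$n_states, 44L)
  # organ compartments carry vascular + extracellular states
  st <- reference_model()$states
  expect_true(all(c("brain.vas", "brain.ec", "liver.vas", "liver.ec")
                  %in% st$state))
})

test_that("model construction rejects broken topologies", {
  bp <- compute_body_parameters(reference_adult())
  cfg <- default_config()
  # venous return re-entering the first-pass pathway is a cycle
  cfg$compartments$cerebral_vein$outflows[[1L]]$recirculation <- NULL
  expect_error(build_model(bp, cfg, recirculation = FALSE), "cycle")
  # ... but is legitimate once recirculation is on
  expect_s3_class(build_model(bp, cfg, recirculation = TRUE),
                  "compartment_model")
})

test_that("bolus input has the protocol's rate and exact total mass", {
  prot <- injection_protocol()
  expect_equal(injection_input(prot, 5), 4 * 370)
  expect_equal(injection_input(prot, 45 / 4), 0)
  expect_equal(injection_input(prot, 30), 0)
  expect_error(injection_input(prot, -1), "t >= 0")

  # quadrature of the rectangle recovers volume x concentration
  mass <- stats::integrate(function(t) injection_input(prot, t),
                           0, 60, subdivisions = 2000L,
                           rel.tol = 1e-10)$value
  expect_equal(mass, 45 * 370, tolerance = 1e-6)
})

test_that("zero dose yields an identically zero curve", {
  prot0 <- injection_protocol(volume = 0)
  cv <- simulate_contrast(reference_model(), prot0, dt_out = 0.5)
  expect_true(all(cv$concentration == 0))
  expect_true(all(cv$amounts == 0))
})

test_that("iodine mass is conserved at every output step", {
  cv <- reference_curve()
  expect_lt(mass_balance_error(cv), 1e-6)
  # before the injection starts nothing is in the system
  expect_equal(unname(total_mass_in_system(cv, 0)), 0)
  expect_equal(unname(total_mass_in_system(cv, 60)), 45 * 370,
               tolerance = 1e-6)
})

test_that("the sink asymptotically captures the whole dose", {
  # the slowest pool (lower-body extracellular space) drains with a time
  # constant of ~20 min, so the asymptote needs a long horizon
  prot <- injection_protocol(scan_delay = 1, scan_duration = 50)
  cv <- simulate_contrast(reference_model(), prot, t_end = 7200, dt_out = 10)
  sink_final <- cv$amounts[nrow(cv$amounts), "sink"]
  expect_gt(sink_final / (45 * 370), 0.99)
  expect_lt(mass_balance_error(cv), 1e-6)
})

test_that("compartment amounts never go negative", {
  cv <- reference_curve()
  expect_gte(min(cv$amounts), -1e-8 * max(cv$amounts))
  expect_gte(min(cv$concentration), 0)
})

test_that("the system is linear in the injected concentration", {
  m <- reference_model()
  base <- reference_curve()
  for (k in c(2, 0.37)) {
    prot_k <- injection_protocol(iodine_concentration = 370 * k)
    cv_k <- simulate_contrast(m, prot_k)
    rel <- max(abs(k * base$concentration - cv_k$concentration)) /
      max(cv_k$concentration)
    expect_lt(rel, 1e-6)
  }
})

test_that("cerebral arterial curve has a single dominant first-pass peak", {
  cv <- reference_curve()
  conc <- cv$concentration[, "cerebral_artery"]
  i_pk <- which.max(conc)
  ttp <- cv$time[i_pk]
  expect_gt(ttp, 10); expect_lt(ttp, 35)
  expect_lt(conc[1L], 1e-6 * conc[i_pk])            # rises from zero
  expect_true(all(diff(conc[1:i_pk]) >= -1e-9 * conc[i_pk]))  # monotone rise
  expect_lt(conc[length(conc)], 0.8 * conc[i_pk])   # decays after peak
  # regression pin of the frozen default topology + physiology
  expect_equal(ttp, 19.0, tolerance = 1e-8)
  expect_equal(unname(conc[i_pk]), 10.624, tolerance = 1e-3)
})

test_that("peak enhancement decreases with body weight at fixed height", {
  mes <- vapply(c(50, 75, 100), function(w) {
    curve <- cached(paste0("wsweep_", w),
                    simulate_patient_tdc(patient_profile("male", 170, w)))
    extract_metrics(curve)$me
  }, numeric(1))
  expect_gt(mes[1L], mes[2L])
  expect_gt(mes[2L], mes[3L])
})

test_that("an organ with zero permeability keeps an empty extracellular space", {
  cv <- reference_curve()  # default brain PS = 0 (intact blood-brain barrier)
  expect_identical(max(abs(cv$amounts[, "brain.ec"])), 0)
  # whereas exchanging organs do fill
  expect_gt(max(cv$amounts[, "liver.ec"]), 0)
})

test_that("the curve is insensitive to solver tolerance and output step", {
  m <- reference_model()
  prot <- injection_protocol()
  me_of <- function(cv) extract_metrics(concentration_to_hu(cv))$me
  cv1 <- reference_curve()
  cv2 <- simulate_contrast(m, prot, rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(me_of(cv1) - me_of(cv2)) / me_of(cv1), 1e-3)
  ttp1 <- cv1$time[which.max(cv1$concentration[, 1L])]
  ttp2 <- cv2$time[which.max(cv2$concentration[, 1L])]
  expect_lte(abs(ttp1 - ttp2), 0.1)

  # dt_out only resamples the solution
  cv3 <- simulate_contrast(m, prot, dt_out = 0.5)
  shared <- match(cv3$time, cv1$time)
  rel <- max(abs(cv3$concentration[, 1L] -
                   cv1$concentration[shared, 1L])) /
    max(cv1$concentration)
  expect_lt(rel, 1e-6)
})

test_that("integrator matches the closed-form two-tank washout", {
  cfg <- two_tank_config()
  bp <- compute_body_parameters(reference_adult(), cfg)
  m <- build_model(bp, cfg)
  expect_identical(m$n_states, 3L)  # tank1, tank2, sink
  prot <- injection_protocol(scan_delay = 1, scan_duration = 24)
  cv <- simulate_contrast(m, prot, t_end = 40)

  u <- prot$rate * prot$iodine_concentration
  k1 <- bp$cardiac_output / bp$regional_blood_volume[["tank1"]]
  k2 <- bp$cardiac_output / bp$regional_blood_volume[["tank2"]]
  exact <- two_tank_analytic(cv$time, u, prot$volume / prot$rate, k1, k2)
  rel <- max(abs(cv$amounts[, c("tank1", "tank2")] - exact)) / max(exact)
  expect_lt(rel, 1e-6)
})

test_that("an injection outlasting the horizon is allowed with a warning", {
  m <- reference_model()
  prot <- injection_protocol(volume = 400, rate = 4, scan_delay = 1,
                             scan_duration = 30)
  expect_warning(cv <- simulate_contrast(m, prot, t_end = 40),
                 "outlasts")
  expect_equal(length(cv$time), 401L)
})
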