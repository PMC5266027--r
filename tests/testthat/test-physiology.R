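test_that("blood volume matches the anthropometric formula and its monotonicity", {
  # hand evaluation of the sex-specific height^3 + weight regression
  expected_ml <- 1000 * (0.3669 * 1.70^3 + 0.03219 * 75 + 0.6041)
  bv <- compute_blood_volume(patient_profile("male", 170, 75))
  expect_equal(bv, expected_ml, tolerance = 1e-12)
  expect_gt(bv, 4500)
  expect_lt(bv, 6500)

  # strictly increasing in weight and height
  expect_gt(compute_blood_volume(patient_profile("male", 170, 100)),
            compute_blood_volume(patient_profile("male", 170, 50)))
  expect_gt(compute_blood_volume(patient_profile("male", 190, 75)),
            compute_blood_volume(patient_profile("male", 160, 75)))

  # sex-specific constants: male exceeds female at equal stature
  expect_gt(bv, compute_blood_volume(patient_profile("female", 170, 75)))
})

test_that("profile validation rejects out-of-range fields by name", {
  expect_error(patient_profile("male", 170, 0), "weight")
  expect_error(patient_profile("male", 90, 75), "height")
  expect_error(patient_profile("person", 170, 75), "sex")
})

test_that("cardiac output scales allometrically with weight", {
  co <- compute_cardiac_output(reference_adult())
  expect_equal(co, (6500 / 60) * (75 / 70)^0.75, tolerance = 1e-12)
  w <- c(40, 60, 80, 120)
  cos <- vapply(w, function(wi)
    compute_cardiac_output(patient_profile("male", 170, wi)), numeric(1))
  expect_true(all(diff(cos) > 0))
})

test_that("body parameters conserve flow and volume", {
  bp <- compute_body_parameters(reference_adult())
  cfg <- default_config()

  # parallel systemic branch flows (aorta outflow edges) sum to cardiac output
  branch_flow <- sum(vapply(cfg$compartments$aorta$outflows,
                            function(e) e$fraction, numeric(1))) *
    bp$cardiac_output
  expect_equal(branch_flow, bp$cardiac_output, tolerance = 1e-9)

  expect_equal(sum(bp$regional_blood_volume), bp$total_blood_volume,
               tolerance = 1e-6)
  expect_true(all(bp$regional_blood_volume > 0))
  expect_true(all(bp$regional_flow > 0))

  # regional flow is CO times the configured through-flow fraction
  expect_equal(unname(bp$regional_flow[["cerebral_artery"]]),
               0.12 * bp$cardiac_output, tolerance = 1e-12)
})

test_that("doubling the cerebral flow fraction doubles cerebral flow only", {
  cfg2 <- scale_cerebral_flow(default_config(), 2)
  bp1 <- compute_body_parameters(reference_adult())
  bp2 <- compute_body_parameters(reference_adult(), cfg2)
  expect_equal(bp2$cardiac_output, bp1$cardiac_output)
  expect_equal(unname(bp2$regional_flow[["cerebral_artery"]]),
               2 * unname(bp1$regional_flow[["cerebral_artery"]]),
               tolerance = 1e-12)
})

test_that("configuration validation catches broken tables", {
  cfg <- default_config()
  cfg$compartments$aorta$outflows[[1L]]$fraction <- 0.2  # unbalances nodes
  expect_error(validate_config(cfg), "unbalanced flows")

  cfg <- default_config()
  cfg$compartments$svc$outflows[[1L]]$target <- "nonexistent"
  expect_error(validate_config(cfg), "unknown compartment name")

  cfg <- default_config()
  cfg$compartments$liver$volume_fraction <- 0.2  # volumes no longer sum to 1
  expect_error(validate_config(cfg), "not summing to 1")
})

test_that("configuration survives a YAML round trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(default_config(), path)
  cfg <- read_config(path)
  bp0 <- compute_body_parameters(reference_adult())
  bp1 <- compute_body_parameters(reference_adult(), cfg)
  expect_equal(bp1$regional_blood_volume, bp0$regional_blood_volume)
  expect_equal(bp1$regional_flow, bp0$regional_flow)
  m <- build_model(bp1, cfg)
  expect_identical(m$n_states, reference_model()$n_states)
})
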