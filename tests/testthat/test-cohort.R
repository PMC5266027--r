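# small cohorts and a coarse output grid keep these unit tests fast; the
# full-size study structure is exercised in the acceptance suite

test_that("cohort generation is deterministic given the seed", {
  spec <- cohort_spec(2, 2, seed = 7)
  c1 <- generate_cohort(spec, dt_out = 0.5)
  c2 <- generate_cohort(spec, dt_out = 0.5)
  expect_identical(lapply(c1$patients, function(p) p$meas_metrics),
                   lapply(c2$patients, function(p) p$meas_metrics))
  expect_identical(c1$patients[[3L]]$meas_tdc$attenuation,
                   c2$patients[[3L]]$meas_tdc$attenuation)
  # counts and sexes match the spec exactly
  sexes <- vapply(c1$patients, function(p) p$profile$sex, character(1))
  expect_identical(sum(sexes == "male"), 2L)
  expect_identical(sum(sexes == "female"), 2L)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(generate_cohort(cohort_spec(1, 1, seed = 9),
                                           dt_out = 1))
  expect_identical(rnorm(3), before)
})

test_that("zero-noise control measurements equal the simulation exactly", {
  spec <- cohort_spec(2, 1, noise_hu = 0, ttp_jitter_s = 0, seed = 3)
  coh <- generate_cohort(spec, dt_out = 0.5)
  for (p in coh$patients) {
    expect_equal(p$meas_metrics$me, p$sim_metrics$me)
    expect_equal(p$meas_metrics$ttp, p$sim_metrics$ttp)
    expect_equal(p$meas_tdc$attenuation, p$sim_tdc$attenuation)
    expect_equal(p$meas_metrics$mtt, spec$mtt_base_s)
  }
})

test_that("the infarct ME factor scales measurements multiplicatively", {
  spec <- cohort_spec(2, 1, group = "infarct", me_factor = 0.8,
                      noise_hu = 0, ttp_jitter_s = 0, seed = 3)
  coh <- generate_cohort(spec, dt_out = 0.5)
  for (p in coh$patients)
    expect_equal(p$meas_metrics$me, 0.8 * p$sim_metrics$me)
})

test_that("empty cohorts are rejected", {
  expect_error(cohort_spec(0, 0), "empty cohort")
})

test_that("paired t matches hand-computed oracles and degenerate contracts", {
  # differences (-0.1, 0.1, -0.2, 0.2): mean 0, hence t = 0, p = 1
  r <- paired_t(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
  expect_equal(r$t_statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)
  expect_equal(r$degrees_of_freedom, 3)

  # differences (4, 4, 3): mean 11/3, sd of differences sqrt(1/3),
  # t = (11/3) / (sqrt(1/3)/sqrt(3)) = 11 by hand
  r2 <- paired_t(c(5, 6, 7), c(1, 2, 4))
  expect_equal(r2$t_statistic, 11, tolerance = 1e-12)
  expect_equal(r2$p_value, 2 * stats::pt(-11, df = 2), tolerance = 1e-12)
  expect_true(r2$significant)

  # identical vectors
  r3 <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$t_statistic, 0); expect_equal(r3$p_value, 1)

  # constant nonzero difference: infinite-t sentinel
  r4 <- paired_t(c(1, 2, 3), c(0, 1, 2))
  expect_identical(r4$t_statistic, Inf)
  expect_identical(r4$p_value, 0)
  expect_true(r4$degenerate)

  expect_error(paired_t(1:3, 1:4), "length mismatch")
})

test_that("two-sample t detects large effects and is antisymmetric", {
  set.seed(5)
  x <- rnorm(50, 0, 1); y <- rnorm(50, 10, 1)
  r <- two_sample_t(x, y)
  expect_lt(r$p_value, 1e-6)

  r_sw <- two_sample_t(y, x)
  expect_equal(r_sw$t_statistic, -r$t_statistic, tolerance = 1e-12)
  expect_equal(r_sw$p_value, r$p_value, tolerance = 1e-12)

  r_id <- two_sample_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r_id$t_statistic, 0); expect_equal(r_id$p_value, 1)
})

test_that("the study's sex imbalance is flagged by the chi-square helper", {
  expect_lt(sex_balance_test(19, 25, 46, 11)$p.value, 0.005)
})

test_that("zero-noise validation reports all-zero paired differences", {
  spec <- cohort_spec(2, 2, noise_hu = 0, ttp_jitter_s = 0, seed = 1)
  rep <- run_validation(generate_cohort(spec, dt_out = 0.5))
  expect_equal(rep$pct_diff[["ME"]], 0)
  expect_equal(rep$pct_diff[["TTP"]], 0)
  expect_equal(rep$comparisons$ME.all$t_statistic, 0)
  expect_equal(rep$comparisons$ME.all$p_value, 1)
  expect_equal(rep$n_excluded, 0)
})

test_that("a cohort of one yields a report with non-computable comparisons", {
  coh <- generate_cohort(cohort_spec(1, 0, seed = 2), dt_out = 0.5)
  rep <- run_validation(coh)
  expect_identical(nrow(rep$table), 1L)
  expect_true(is.na(rep$comparisons$ME.all$p_value))
  expect_equal(rep$comparisons$ME.all$degrees_of_freedom, 0)
})

test_that("noise replication machinery estimates power sensibly", {
  # huge effect, tiny noise: always rejected
  expect_equal(replicate_paired_tests(rep(400, 10), 20, noise_hu = 1,
                                      me_factor = 0.5, seed = 1), 1)
  # null with absurdly generous alpha rejects most of the time
  expect_gt(replicate_paired_tests(rep(400, 10), 50, noise_hu = 30,
                                   me_factor = 1, alpha = 0.9, seed = 1),
            0.5)
})
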