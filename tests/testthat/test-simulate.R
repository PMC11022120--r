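test_that("cohort model validates its parameters", {
  expect_s3_class(cohort_model(), "cohort_model")
  expect_error(cohort_model(n_eyes = 1), "n_eyes")
  expect_error(cohort_model(baseline_sd = -1), "non-negative")
  expect_error(cohort_model(loss_fraction_m2 = 1), "loss fractions")
  expect_error(cohort_model(within_eye_correlation = 1), "correlation")
  expect_error(cohort_model(treatment_effect = 1.5), "treatment_effect")
})

test_that("noiseless generation is the deterministic proportional-loss model", {
  m <- cohort_model(
    n_eyes = 8, baseline_sd = 0.01,
    residual_sd_m2 = 0, residual_sd_m6 = 0, within_eye_correlation = 0
  )
  co <- generate_cohort(m, seed = 4)
  wide <- co |>
    dplyr::filter(metric == "volume") |>
    tidyr::pivot_wider(names_from = timepoint, values_from = value)
  expect_equal(wide$m2, wide$baseline * (1 - 0.30), tolerance = 1e-12)
  expect_equal(wide$m6, wide$baseline * (1 - 0.37), tolerance = 1e-12)

  # full protection keeps follow-up at baseline
  prot <- generate_cohort(
    cohort_model(
      n_eyes = 6, residual_sd_m2 = 0, residual_sd_m6 = 0,
      treatment_effect = 1
    ),
    seed = 4
  )
  widep <- prot |>
    dplyr::filter(metric == "volume") |>
    tidyr::pivot_wider(names_from = timepoint, values_from = value)
  expect_equal(widep$m2, widep$baseline, tolerance = 1e-12)
  expect_equal(widep$m6, widep$baseline, tolerance = 1e-12)
})

test_that("generation is reproducible from the seed and feeds the summaries", {
  m <- cohort_model(n_eyes = 20)
  a <- generate_cohort(m, seed = 99)
  b <- generate_cohort(m, seed = 99)
  c <- generate_cohort(m, seed = 100)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$value, c$value)))
  expect_equal(nrow(a), 20 * 3 * 2)
  expect_s3_class(summarize_metric(a, "volume", "m2"), "tbl_df")
})

test_that("large synthetic cohorts recover the generating parameters", {
  m <- cohort_model(
    n_eyes = 10000, baseline_mean = 0.534, baseline_sd = 0.134,
    loss_fraction_m2 = 0.30, loss_fraction_m6 = 0.37,
    residual_sd_m2 = 0.03, residual_sd_m6 = 0.03
  )
  co <- generate_cohort(m, seed = 2718)
  tol_b <- 3 * m$baseline_sd / sqrt(m$n_eyes)
  sb <- summarize_metric(co, "volume", "baseline")
  expect_lt(abs(sb$mean - 0.534), tol_b)
  expect_lt(abs(sb$sd - 0.134), 3 * m$baseline_sd / sqrt(2 * m$n_eyes))

  s2 <- summarize_metric(co, "volume", "m2")
  sd_m2 <- sqrt((0.70 * m$baseline_sd)^2 + m$residual_sd_m2^2)
  expect_lt(abs(s2$mean - 0.534 * 0.70), 3 * sd_m2 / sqrt(m$n_eyes))

  s6 <- summarize_metric(co, "volume", "m6")
  sd_m6 <- sqrt((0.63 * m$baseline_sd)^2 + m$residual_sd_m6^2)
  expect_lt(abs(s6$mean - 0.534 * 0.63), 3 * sd_m6 / sqrt(m$n_eyes))

  # follow-up residuals share the eye-level component at the set correlation
  wide <- co |>
    dplyr::filter(metric == "volume") |>
    tidyr::pivot_wider(names_from = timepoint, values_from = value) |>
    dplyr::mutate(r2 = m2 - 0.70 * baseline, r6 = m6 - 0.63 * baseline)
  expect_equal(cor(wide$r2, wide$r6), 0.7, tolerance = 0.05)
})

test_that("simulated rejection rate is calibrated under the null", {
  rep0 <- simulate_trial_power(
    n_test = 103, n_gc = 103, gc_mean = 0.198, test_mean = 0.198,
    sigma = 0.10134, replicates = 10000, seed = 31
  )
  expect_lt(abs(rep0$empirical_power - 0.05), 4 * sqrt(0.05 * 0.95 / 10000))
  expect_false(rep0$flagged)
})

test_that("empirical power matches the analytic formula on the pilot designs", {
  co <- oct_cohort()

  # headline change-score design: 103 per arm, ~80% power
  headline <- estimate_sample_size(co, "volume", "m6", "B", effect_size = 0.20)
  rep1 <- simulate_design(headline, replicates = 100000, seed = 12)
  expect_lt(
    abs(rep1$empirical_power - rep1$analytic_power),
    4 * rep1$mc_se
  )
  expect_gt(rep1$empirical_power, 0.79)

  # worked follow-up design: 131 per arm
  worked <- estimate_sample_size(co, "volume", "m2", "A", effect_size = 0.20)
  rep2 <- simulate_design(worked, replicates = 100000, seed = 13)
  expect_lt(abs(rep2$empirical_power - rep2$analytic_power), 4 * rep2$mc_se)

  # Welch-t route agrees at these arm sizes (t vs z difference is tiny)
  rep3 <- simulate_design(headline, replicates = 5000, seed = 14, test = "welch")
  expect_lt(abs(rep3$empirical_power - rep3$analytic_power), 0.02)
})

test_that("end_to_end validates every cell of a grid against simulation", {
  out <- end_to_end(
    cohort_model(n_eyes = 60, residual_sd_m2 = 0.02, residual_sd_m6 = 0.02),
    seed = 8, replicates = 4000,
    effect_sizes = c(0.2, 0.4), powers = c(0.8, 0.9)
  )
  expect_equal(nrow(out), 16) # 2 effects x 2 powers x 2 methods x 2 visits
  expect_true(all(out$achieved_power >= out$power_target))
  expect_true(all(
    abs(out$empirical_power - out$achieved_power) <= 4 * out$mc_se
  ))

  # deterministic under reuse of the same seed
  again <- end_to_end(
    cohort_model(n_eyes = 60, residual_sd_m2 = 0.02, residual_sd_m6 = 0.02),
    seed = 8, replicates = 4000,
    effect_sizes = c(0.2, 0.4), powers = c(0.8, 0.9)
  )
  expect_identical(out, again)
})

test_that("simulator rejects undersized inputs", {
  expect_error(
    simulate_trial_power(10, 10, 1, 0.5, sigma = 1, replicates = 10),
    "replicates"
  )
  expect_error(
    simulate_trial_power(10, 10, 1, 0.5, sigma = 0, replicates = 1000),
    "sigma"
  )
})
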