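test_that("linear-threshold generator is deterministic given a seed", {
  a <- simulate_linear_threshold_cohorts(seed = 11)
  b <- simulate_linear_threshold_cohorts(seed = 11)
  expect_identical(a, b)
  c <- simulate_linear_threshold_cohorts(seed = 12)
  expect_false(identical(a, c))
})

test_that("degenerate generator settings censor the response", {
  # zero slope: no cases, survival 1 everywhere
  z <- simulate_linear_threshold_cohorts(
    ce = c(50, 100, 400), tm = 5000, slope_pct = 0, seed = 1
  )
  expect_true(all(z$meso_cases == 0))
  expect_true(all(z$survival == 1))

  # threshold above every exposure: all cohorts below threshold
  t <- simulate_linear_threshold_cohorts(
    ce = c(50, 100, 400), tm = 5000, slope_pct = 0.01, threshold = 1000,
    seed = 1
  )
  expect_true(all(t$meso_cases == 0))

  # overflow guard: rate above 1 is an error
  expect_error(simulate_linear_threshold_cohorts(
    ce = c(50, 100, 40000), tm = 100, slope_pct = 0.01, threshold = 0,
    seed = 1
  ))
})

test_that("generated counts match the stated Poisson mean (law of large numbers)", {
  # published cohort sizes, slope 0.0016 %/f/cc-yr, threshold 25:
  # expected percent excess at CE = 600 is 0.0016 * 575 = 0.92
  tab1 <- cohort_table1()
  n_rep <- 400
  draws <- vapply(seq_len(n_rep), function(i) {
    g <- simulate_linear_threshold_cohorts(
      ce = tab1$cumulative_fcc_years, tm = tab1$expected_mortality,
      slope_pct = 0.0016, threshold = 25, exposure_error = 0.3,
      seed = 20000 + i
    )
    100 * g$meso_cases[1] / g$expected_mortality[1]
  }, numeric(1))
  expected_pct <- 0.0016 * (600 - 25)
  # Poisson mean m = 0.0092 * 5913 ~ 54.4; SE of the percent mean follows
  se <- 100 * sqrt(expected_pct / 100 * 5913) / 5913 / sqrt(n_rep)
  expect_lt(abs(mean(draws) - expected_pct), 3 * se)
})

test_that("exposure error perturbs reported but not latent exposure", {
  g <- simulate_linear_threshold_cohorts(
    ce = c(100, 200, 400), tm = 1e5, slope_pct = 0.002, threshold = 50,
    exposure_error = 0.3, seed = 5
  )
  expect_false(all(g$cumulative_fcc_years == g$latent_ce))
  expect_true(all(
    abs(g$cumulative_fcc_years - g$latent_ce) <= 0.3 * g$latent_ce
  ))
  # true rate is computed from the latent exposure
  expect_equal(g$true_rate, pmax(0, 0.002 * (g$latent_ce - 50)) / 100)
})

test_that("lifetime-risk generator reproduces the closed-form Poisson mean", {
  tab1 <- cohort_table1()
  designs <- dplyr::select(
    tab1, intensity_fcc, duration_years, onset_age, expected_mortality
  )
  g <- simulate_peto_cohorts(peto_params(), designs, seed = 2)
  # Quebec: risk ~ 0.0055 so mean count ~ 33
  expect_equal(g$true_risk[1] * g$expected_mortality[1], 32.7, tolerance = 0.01)
  expect_identical(g, simulate_peto_cohorts(peto_params(), designs, seed = 2))

  # threshold above every intensity^p: nothing is generated
  high_th <- peto_params(threshold = 1e6)
  g0 <- simulate_peto_cohorts(high_th, designs, seed = 2)
  expect_true(all(g0$meso_cases == 0))

  # zero duration: degenerate exposure window
  d0 <- dplyr::mutate(designs, duration_years = 0)
  expect_true(all(
    simulate_peto_cohorts(peto_params(), d0, seed = 2)$meso_cases == 0
  ))

  # observation window must open before lifespan
  bad <- dplyr::mutate(designs, onset_age = 90)
  expect_error(simulate_peto_cohorts(peto_params(), bad, seed = 2))
})
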