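test_that("excess-line OLS matches the normal-equation oracle", {
  tab <- cohort_table1()
  fit <- fit_excess_line(tab)
  X <- cbind(1, tab$cumulative_fcc_years)
  co <- ols_oracle(X, 100 * tab$excess_rate)
  expect_equal(fit$intercept, co[1], tolerance = 1e-12)
  expect_equal(fit$slope, co[2], tolerance = 1e-12)
  # central fit of the published cohorts: A ~ -0.043, B ~ 0.00147, -A/B ~ 29
  expect_equal(fit$intercept, -0.0426, tolerance = 0.01)
  expect_equal(fit$slope, 0.00147, tolerance = 0.01)
  expect_equal(threshold_estimate(fit), 29.0, tolerance = 0.01)
})

test_that("excess-line OLS reproduces exact and degenerate lines", {
  toy <- toy_cohorts(ce = c(10, 20, 40, 80))
  fit <- fit_excess_line(toy, y = 2 + 3 * toy$cumulative_fcc_years)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(fit$slope, 3, tolerance = 1e-10)

  flat <- fit_excess_line(toy, y = rep(7, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$intercept, 7)

  same_ce <- toy_cohorts(ce = c(50, 50, 50, 50))
  expect_error(fit_excess_line(same_ce), class = "mesothresh_singular_error")
})

test_that("threshold classification follows the sign rule strictly", {
  expect_true(is_threshold_fit(c(-0.04, 0.0015)))
  expect_false(is_threshold_fit(c(0.1, 0.001)))
  expect_false(is_threshold_fit(c(-1, 0))) # B > 0 is strict
  expect_true(is_threshold_fit(c(0, 1))) # A <= 0 is inclusive

  expect_equal(threshold_estimate(c(-1, 0.5)), 2)
  expect_equal(threshold_estimate(c(0, 1)), 0)
  expect_error(
    threshold_estimate(c(0.1, 1)),
    class = "mesothresh_contract_error"
  )
})

test_that("Monte Carlo is reproducible and collapses under zero noise", {
  tab <- cohort_table1()
  a <- run_threshold_mc(tab, n_iter = 200, seed = 42)
  b <- run_threshold_mc(tab, n_iter = 200, seed = 42)
  expect_identical(tidy(a), tidy(b))

  # zero jitter + no response noise: every iteration equals the central fit
  central <- fit_excess_line(tab)
  mc0 <- run_threshold_mc(tab,
    n_iter = 50, exposure_jitter = 0,
    response_draw = "none", seed = 1
  )
  d <- tidy(mc0)
  expect_equal(d$intercept, rep(central$intercept, 50), tolerance = 1e-9)
  expect_equal(d$slope, rep(central$slope, 50), tolerance = 1e-9)
  expect_equal(mc0$fraction_threshold, 1)
  expect_equal(mc0$mean_threshold, threshold_estimate(central),
    tolerance = 1e-9
  )
})

test_that("Monte Carlo summaries are coherent and spread grows with jitter", {
  tab <- cohort_table1()
  mc <- run_threshold_mc(tab, n_iter = 2000, seed = 7)
  g <- glance(mc)
  expect_true(g$p5 <= g$mean_threshold && g$mean_threshold <= g$p95)
  expect_true(g$fraction_threshold >= 0 && g$fraction_threshold <= 1)
  expect_equal(g$n_threshold, sum(tidy(mc)$threshold_relationship))
  expect_true(g$ci_low < g$mean_threshold && g$mean_threshold < g$ci_high)

  wide <- run_threshold_mc(tab,
    n_iter = 2000, exposure_jitter = 0.6, seed = 7
  )
  expect_gte(wide$p95 - wide$p5, g$p95 - g$p5)
})

test_that("all-zero count draws are retained as non-threshold fits", {
  # tiny expected counts: most draws are all-zero -> A = B = 0, not threshold
  toy <- toy_cohorts(ce = c(10, 50, 100, 200), cases = c(0, 0, 0, 0))
  mc <- run_threshold_mc(toy,
    n_iter = 100, response_draw = "expected", seed = 3
  )
  d <- tidy(mc)
  expect_equal(nrow(d), 100)
  expect_equal(mc$fraction_threshold, 0)
  expect_true(all(d$slope == 0))
})

test_that("Monte Carlo recovers a known threshold from synthetic cohorts", {
  truth_thr <- 30
  truth_slope <- 0.004
  tabs <- lapply(1:8, function(i) {
    simulate_linear_threshold_cohorts(
      ce = c(20, 60, 120, 250, 400, 700),
      tm = 20000, slope_pct = truth_slope, threshold = truth_thr,
      exposure_error = 0, seed = 1000 + i
    )
  })
  means <- vapply(tabs, function(tt) {
    run_threshold_mc(tt,
      n_iter = 400, response_draw = "expected", seed = 5
    )$mean_threshold
  }, numeric(1))
  # averaged over replicates the MC mean threshold brackets the truth
  expect_equal(mean(means), truth_thr, tolerance = 0.35)
})
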