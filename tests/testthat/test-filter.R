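test_that("filter fit equals the closed-form normal-equation solution", {
  tab <- cohort_table1()
  fit <- fit_filter(tab)
  u <- log(tab$cumulative_fcc_years + 1)
  co <- ols_oracle(cbind(1, u, u^2), 1 - tab$excess_rate)
  expect_equal(fit$c, co[1], tolerance = 1e-10)
  expect_equal(fit$a, co[2], tolerance = 1e-10)
  expect_equal(fit$b, co[3], tolerance = 1e-10)
})

test_that("published cohorts give the published coefficient roundings", {
  fit <- fit_filter(cohort_table1(), s_source = "unrounded")
  expect_equal(round(fit$a, 3), 0.014)
  expect_equal(round(fit$b, 5), -0.0017)
  expect_equal(fit$b, -0.00168, tolerance = 0.011)
  expect_equal(round(fit$c, 3), 0.972)
  expect_equal(fit$pearson_r, 0.91, tolerance = 0.005)
  expect_equal(fit$r_squared, 0.83, tolerance = 0.005)
  # the implied inflection threshold lands in the low 160s f/cc-years
  expect_equal(fit$threshold, 162, tolerance = 0.03)

  # the printed survival column differs only through rounding
  fit_printed <- fit_filter(cohort_table1(), s_source = "printed")
  expect_equal(fit_printed$c, fit$c, tolerance = 0.002)
})

test_that("noiseless quadratic survival data are recovered to machine precision", {
  a0 <- 0.01
  b0 <- -0.002
  c0 <- 0.95
  ce <- c(10, 50, 150, 400, 700)
  u <- log(ce + 1)
  s <- c0 + a0 * u + b0 * u^2
  tab <- toy_cohorts(ce = ce, cases = rep(0, 5))
  tab$excess_rate <- 1 - s
  tab$survival <- s
  fit <- fit_filter(tab)
  expect_equal(fit$a, a0, tolerance = 1e-10)
  expect_equal(fit$b, b0, tolerance = 1e-10)
  expect_equal(fit$c, c0, tolerance = 1e-10)

  # constant survival: quadratic vanishes, threshold flagged undefined
  flat <- toy_cohorts(ce = ce, cases = rep(0, 5))
  expect_warning(ff <- fit_filter(flat), "undefined")
  expect_equal(ff$a, 0, tolerance = 1e-12)
  expect_equal(ff$b, 0, tolerance = 1e-12)
  expect_equal(ff$c, 1, tolerance = 1e-12)
  expect_true(is.na(ff$threshold))
})

test_that("threshold formula follows exp(1 - a/(2b)) exactly", {
  expect_equal(filter_threshold(0, -1), exp(1))
  # rounding the published coefficients shifts the threshold noticeably
  expect_equal(
    filter_threshold(0.014, -0.00168),
    exp(1 + 0.014 / (2 * 0.00168))
  )
  expect_equal(filter_threshold(0.014, -0.00168), 175.2, tolerance = 0.001)
  expect_error(filter_threshold(0.01, 0), class = "mesothresh_contract_error")

  # monotone in a for fixed b < 0
  as <- seq(0.005, 0.03, by = 0.005)
  expect_true(!is.unsorted(filter_threshold(as, -0.002)))
})

test_that("second derivative vanishes at the analytic inflection exposure", {
  fit <- fit_filter(cohort_table1())
  root <- exp(1 - fit$a / (2 * fit$b)) - 1
  expect_equal(filter_second_derivative(fit, root), 0, tolerance = 1e-15)
  expect_equal(fit$inflection, fit$threshold - 1)
  # concave (negative) below the inflection, convex above
  expect_lt(filter_second_derivative(fit, 50), 0)
  expect_gt(filter_second_derivative(fit, root + 50), 0)
  expect_equal(filter_second_derivative(c(0, -1), exp(1) - 1), 0,
    tolerance = 1e-15
  )
})

test_that("single-anchor simulation matches its closed-form degenerate cases", {
  # a = 1.0, c = 0.95: b = (0.97 - 0.95 - 2.77)/7.67, threshold 10.96
  one <- simulate_laa_anchor(
    c_range = c(0.95, 0.95), a_range = c(1, 1), n_draws = 10, seed = 1
  )
  expect_equal(one$sd, 0)
  expect_equal(one$mean, exp(1 - 1 / (2 * (0.97 - 0.95 - 2.77) / 7.67)))
  expect_equal(one$mean, 10.96, tolerance = 1e-3)

  two <- simulate_laa_anchor(
    c_range = c(0.9, 0.9), a_range = c(-0.87, -0.87), n_draws = 10, seed = 1
  )
  expect_equal(two$mean, 10.44, tolerance = 1e-3)
})

test_that("single-anchor simulation is seeded and stable across seeds", {
  a <- simulate_laa_anchor(n_draws = 4000, seed = 9)
  b <- simulate_laa_anchor(n_draws = 4000, seed = 9)
  expect_identical(tidy(a), tidy(b))
  expect_equal(a$n_kept + a$n_discarded, 4000)
  expect_true(all(tidy(a)$threshold <= a$threshold_cap))

  means <- vapply(
    1:5,
    function(s) simulate_laa_anchor(n_draws = 4000, seed = s)$mean,
    numeric(1)
  )
  expect_lt(diff(range(means)) / mean(means), 0.05)
})
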