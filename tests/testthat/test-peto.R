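test_that("closed-form lifetime risk equals numerical quadrature", {
  # oracle: integrate the piecewise age-response kernel directly
  risk_quadrature <- function(p, e, d, y) {
    dose <- max(0, e^p$power - p$threshold)
    upper <- p$lifespan - y
    if (upper <= p$lag) {
      return(0)
    }
    during <- stats::integrate(
      function(t) dose * (t - p$lag)^3,
      lower = p$lag, upper = min(p$lag + d, upper), rel.tol = 1e-12
    )$value
    after <- if (upper > p$lag + d) {
      stats::integrate(
        function(t) dose * ((t - p$lag)^3 - (t - p$lag - d)^3),
        lower = p$lag + d, upper = upper, rel.tol = 1e-12
      )$value
    } else {
      0
    }
    p$k_m * (during + after)
  }
  set.seed(99)
  for (i in 1:25) {
    p <- peto_params(
      k_m = runif(1, 1e-12, 1e-9),
      lifespan = runif(1, 70, 100),
      threshold = runif(1, 0, 5),
      power = runif(1, 1, 2),
      lag = runif(1, 5, 20)
    )
    e <- runif(1, 0, 50)
    d <- runif(1, 0, 50)
    y <- runif(1, 15, 40)
    closed <- peto_risk(p, e, d, y)
    quad <- risk_quadrature(p, e, d, y)
    if (quad > 0) {
      expect_equal(closed, quad, tolerance = 1e-9)
    } else {
      expect_equal(closed, 0)
    }
  }
})

test_that("published parameters reproduce the Quebec risk and cohort correlation", {
  p <- peto_params() # K_M = 0.0042e-8, V = 85.9, Th = 2.8, p = 1.5, lag 10
  expect_equal(
    peto_risk(p, intensity = 17.14, duration = 35, onset_age = 23),
    0.00553,
    tolerance = 0.001
  )
  ev <- fit_peto(cohort_table1(), params = p)
  expect_equal(ev$pearson_r, 0.993, tolerance = 0.001)
  expect_false(ev$fitted)
})

test_that("lifetime risk honours the threshold clamp and degenerate windows", {
  p <- peto_params()
  # intensity below the threshold in transformed units
  expect_equal(peto_risk(p, intensity = 1.9, duration = 30, onset_age = 20), 0)
  expect_equal(peto_risk(p, intensity = 10, duration = 0, onset_age = 20), 0)
  # no observable window once onset + lag passes the lifespan
  expect_equal(peto_risk(p, intensity = 10, duration = 5, onset_age = 80), 0)
  expect_error(peto_risk(p, intensity = -1, duration = 5, onset_age = 30))
})

test_that("lifetime risk is monotone in intensity, duration and lifespan", {
  base <- peto_params()
  es <- seq(0, 50, by = 2.5)
  expect_true(!is.unsorted(peto_risk(base, es, 20, 25)))
  ds <- seq(0, 40, by = 2)
  expect_true(!is.unsorted(peto_risk(base, 10, ds, 25)))
  vs <- seq(70, 100, by = 2)
  risks <- vapply(
    vs,
    function(v) {
      peto_risk(peto_params(lifespan = v), 10, 20, 25)
    },
    numeric(1)
  )
  expect_true(!is.unsorted(risks))
})

test_that("grid fit recovers noiseless self-generated parameters", {
  truth <- peto_params(k_m = 0.004e-8, lifespan = 86, threshold = 2.5)
  tab <- toy_cohorts(
    ce = c(600, 721, 120, 46, 33.6),
    cases = c(0, 0, 0, 0, 0)
  )
  tab$intensity_fcc <- c(17.14, 42.5, 4.39, 5.72, 2.24)
  tab$duration_years <- c(35, 16.95, 27.3, 8.04, 15)
  tab$onset_age <- c(23, 27, 21.7, 31, 24)
  tab$excess_rate <- peto_risk(
    truth, tab$intensity_fcc, tab$duration_years, tab$onset_age
  )
  tab$survival <- 1 - tab$excess_rate
  fit <- fit_peto(tab,
    lifespan_grid = seq(80, 90, by = 0.1),
    threshold_grid = seq(0, 3, by = 0.01)
  )
  expect_equal(fit$params$lifespan, 86, tolerance = 1e-9)
  expect_equal(fit$params$threshold, 2.5, tolerance = 1e-9)
  expect_equal(fit$params$k_m, 0.004e-8, tolerance = 1e-6)
  expect_equal(fit$sse, 0, tolerance = 1e-20)
})

test_that("fitted optimum is at least as good as the published point", {
  tab <- cohort_table1()
  published <- fit_peto(tab, params = peto_params())
  fitted <- fit_peto(tab)
  expect_lte(fitted$sse, published$sse)
  expect_gte(fitted$pearson_r, 0.993)
})

test_that("threshold unit conversions follow the stated arithmetic", {
  expect_equal(intensity_threshold(2.8, 1.5), 2.8^(1 / 1.5))
  expect_equal(intensity_threshold(2.8, 1.5), 1.986, tolerance = 1e-3)
  expect_equal(intensity_threshold(2.0, 1.8), 1.47, tolerance = 1e-2)
  expect_equal(intensity_threshold(1, 7.3), 1)
  expect_equal(cumulative_threshold(2, 45), 90)
  expect_equal(cumulative_threshold(0, 45), 0)
  expect_equal(cumulative_threshold(1.5, 45), 67.5)
})
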