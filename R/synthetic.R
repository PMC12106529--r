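#' Run code with a temporarily seeded random-number generator
#'
#' All stochastic functions in the package take an explicit `seed`; the
#' global RNG state is restored afterwards so library code never perturbs a
#' user's stream.
#'
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate cohort tables from a linear-threshold excess-mortality model
#'
#' Generates synthetic occupational cohorts with the statistical structure
#' assumed by the Monte Carlo threshold analysis: each cohort's true excess
#' mesothelioma rate is a hockey-stick function of cumulative exposure,
#' `max(0, slope_pct * (CE - threshold)) / 100`, observed case counts are
#' Poisson with mean `rate * expected_mortality`, and the *reported*
#' cumulative exposure may carry uniform multiplicative assessment error.
#' Poisson means always use the latent (error-free) exposure; the jitter
#' models exposure-assessment error, not true-dose variation.
#'
#' @param ce Latent cumulative exposures, f/cc-years. If `NULL`,
#'   `n_cohorts` values are drawn log-uniformly over `ce_range`.
#' @param tm Expected total mortality per cohort; recycled to the number of
#'   cohorts.
#' @param slope_pct True excess slope, percent excess mortality per
#'   f/cc-year (must be >= 0).
#' @param threshold True cumulative-exposure threshold, f/cc-years.
#' @param exposure_error Half-width of the uniform multiplicative error on
#'   reported exposure (0.3 means reported CE is uniform on 70%-130% of the
#'   latent CE). Use 0 for exact reporting.
#' @param n_cohorts Number of cohorts when `ce` is sampled.
#' @param ce_range Range for log-uniform exposure sampling, f/cc-years.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A cohort tibble (see [cohort-tables]) with `excess_rate` and
#'   `survival` recomputed from the drawn counts, plus columns
#'   `latent_ce` and `true_rate` recording the generating state.
#' @export
#' @examples
#' simulate_linear_threshold_cohorts(
#'   ce = c(50, 100, 200, 400), tm = 2000,
#'   slope_pct = 0.0016, threshold = 25, seed = 1
#' )
simulate_linear_threshold_cohorts <- function(ce = NULL, tm = 1000,
                                              slope_pct = 0.0016,
                                              threshold = 25,
                                              exposure_error = 0.30,
                                              n_cohorts = 6,
                                              ce_range = c(10, 1000),
                                              seed = NULL) {
  if (slope_pct < 0) abort("`slope_pct` must be non-negative.")
  if (threshold < 0) abort("`threshold` must be non-negative.")
  if (exposure_error < 0 || exposure_error >= 1) {
    abort("`exposure_error` must lie in [0, 1).")
  }
  with_seed(seed, {
    if (is.null(ce)) {
      if (n_cohorts < 2) abort("`n_cohorts` must be at least 2.")
      ce <- exp(runif(n_cohorts, log(ce_range[1]), log(ce_range[2])))
    }
    n <- length(ce)
    if (n < 2) abort("at least two cohorts are required.")
    tm <- rep_len(tm, n)
    rate <- pmax(0, slope_pct * (ce - threshold)) / 100
    if (any(rate > 1)) {
      abort("excess rate exceeds 1; reduce `slope_pct` or exposures.")
    }
    cases <- rpois(n, rate * tm)
    reported <- ce * runif(n, 1 - exposure_error, 1 + exposure_error)
    duration <- rep(20, n)
    tibble::tibble(
      name = sprintf("synthetic-%02d", seq_len(n)),
      duration_years = duration,
      intensity_fcc = reported / duration,
      cumulative_fcc_years = reported,
      onset_age = rep(25, n),
      meso_cases = as.numeric(cases),
      expected_mortality = tm,
      excess_rate = cases / tm,
      survival = 1 - cases / tm,
      latent_ce = ce,
      true_rate = rate
    )
  })
}

#' Simulate cohort tables from the threshold-extended lifetime-risk model
#'
#' Draws mesothelioma case counts for a set of exposure designs under the
#' threshold-extended Peto lifetime-risk model (see [peto_risk()]): each
#' row's expected excess rate is the closed-form lifetime risk at its
#' intensity, duration and onset age, and observed counts are Poisson with
#' mean `risk * expected_mortality`. Negative risk increments (intensity
#' below the threshold) are clamped to zero, so sub-threshold designs never
#' generate cases.
#'
#' @param params A [peto_params()] object.
#' @param designs A data frame with columns `intensity_fcc`,
#'   `duration_years`, `onset_age` and `expected_mortality`.
#' @param seed Integer seed.
#' @return A cohort tibble (see [cohort-tables]) with an extra `true_risk`
#'   column holding the generating lifetime risk.
#' @export
#' @examples
#' simulate_peto_cohorts(
#'   peto_params(),
#'   dplyr::select(
#'     cohort_table1(),
#'     intensity_fcc, duration_years, onset_age, expected_mortality
#'   ),
#'   seed = 1
#' )
simulate_peto_cohorts <- function(params, designs, seed = NULL) {
  stopifnot(inherits(params, "peto_params"))
  need <- c(
    "intensity_fcc", "duration_years", "onset_age", "expected_mortality"
  )
  missing <- setdiff(need, names(designs))
  if (length(missing) > 0) {
    abort(paste0(
      "`designs` is missing column(s): ",
      paste0("`", missing, "`", collapse = ", ")
    ))
  }
  if (any(designs$onset_age + params$lag >= params$lifespan)) {
    abort("every design must satisfy onset_age + lag < lifespan.")
  }
  with_seed(seed, {
    risk <- peto_risk(
      params,
      intensity = designs$intensity_fcc,
      duration = designs$duration_years,
      onset_age = designs$onset_age
    )
    tm <- designs$expected_mortality
    cases <- rpois(nrow(designs), risk * tm)
    tibble::tibble(
      name = sprintf("synthetic-%02d", seq_len(nrow(designs))),
      duration_years = designs$duration_years,
      intensity_fcc = designs$intensity_fcc,
      cumulative_fcc_years = designs$intensity_fcc * designs$duration_years,
      onset_age = designs$onset_age,
      meso_cases = as.numeric(cases),
      expected_mortality = tm,
      excess_rate = cases / tm,
      survival = 1 - cases / tm,
      true_risk = risk
    )
  })
}
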