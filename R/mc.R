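#' Fit the linear excess-mortality model to a cohort table
#'
#' Ordinary least squares of excess mesothelioma mortality, expressed in
#' percent of expected deaths, on cumulative exposure:
#'
#'   100 * M / TM = A + B * CE
#'
#' The intercept A (percent) and slope B (percent per f/cc-year) carry the
#' threshold information: a fit with `A <= 0` and `B > 0` crosses zero at a
#' positive exposure `-A/B`, the threshold estimate.
#'
#' @param data A cohort table (see [cohort-tables]) with at least three
#'   rows and non-constant cumulative exposure.
#' @param y Optional response vector (percent excess mortality); defaults
#'   to `100 * excess_rate`.
#' @return An object of class `excess_line` with components `intercept`,
#'   `slope`, and a `data` tibble of (exposure, observed, fitted) values.
#' @seealso [is_threshold_fit()], [threshold_estimate()],
#'   [run_threshold_mc()]
#' @export
#' @examples
#' fit_excess_line(cohort_table1())
fit_excess_line <- function(data, y = NULL) {
  data <- check_cohorts(data)
  if (nrow(data) < 3) abort("at least three cohorts are required.")
  ce <- data$cumulative_fcc_years
  y <- y %||% (100 * data$excess_rate)
  if (length(y) != length(ce)) abort("`y` must match the number of cohorts.")
  co <- ols_line(ce, y)
  structure(
    list(
      intercept = co[["intercept"]],
      slope = co[["slope"]],
      data = tibble::tibble(
        name = data$name,
        cumulative_fcc_years = ce,
        observed = y,
        fitted = co[["intercept"]] + co[["slope"]] * ce
      )
    ),
    class = "excess_line"
  )
}

# closed-form simple linear regression (normal equations)
ols_line <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    abort("degenerate design: exposures are all equal.",
      class = "mesothresh_singular_error"
    )
  }
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - b * mean(x), slope = b)
}

#' @export
print.excess_line <- function(x, ...) {
  cat("Linear excess-mortality fit: 100 M/TM = A + B CE\n")
  cat(sprintf(
    "  A = %.5g %%   B = %.5g %% per f/cc-year\n", x$intercept, x$slope
  ))
  if (is_threshold_fit(x)) {
    cat(sprintf(
      "  threshold relationship: -A/B = %.4g f/cc-years\n",
      threshold_estimate(x)
    ))
  } else {
    cat("  not a threshold relationship (needs A <= 0 and B > 0)\n")
  }
  invisible(x)
}

#' @export
tidy.excess_line <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.excess_line <- function(x, ...) {
  tibble::tibble(
    intercept = x$intercept,
    slope = x$slope,
    threshold_relationship = is_threshold_fit(x),
    threshold = if (is_threshold_fit(x)) threshold_estimate(x) else NA_real_,
    r_squared = stats::cor(x$data$observed, x$data$fitted)^2,
    n = nrow(x$data)
  )
}

#' Classify a linear fit as a threshold relationship
#'
#' A fitted excess-mortality line represents a threshold relationship when
#' the intercept is non-positive and the slope strictly positive, so the
#' line crosses zero excess at a non-negative exposure.
#'
#' @param fit An `excess_line` object, or a length-2 numeric
#'   `c(intercept, slope)`.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' is_threshold_fit(c(-0.04, 0.0015)) # TRUE
#' is_threshold_fit(c(-1, 0)) # FALSE: slope must be strictly positive
is_threshold_fit <- function(fit) {
  ab <- fit_ab(fit)
  ab[[1]] <= 0 && ab[[2]] > 0
}

#' Threshold estimate from a threshold-classified linear fit
#'
#' The exposure at which the fitted line crosses zero excess, `-A/B`
#' (f/cc-years). Only defined for threshold relationships
#' ([is_threshold_fit()]).
#'
#' @inheritParams is_threshold_fit
#' @return Threshold in f/cc-years (>= 0).
#' @export
#' @examples
#' threshold_estimate(c(-1, 0.5)) # 2
threshold_estimate <- function(fit) {
  ab <- fit_ab(fit)
  if (!is_threshold_fit(ab)) {
    abort(
      "threshold estimate is only defined when A <= 0 and B > 0.",
      class = "mesothresh_contract_error"
    )
  }
  -ab[[1]] / ab[[2]]
}

fit_ab <- function(fit) {
  if (inherits(fit, "excess_line")) {
    c(fit$intercept, fit$slope)
  } else if (is.numeric(fit) && length(fit) == 2) {
    as.numeric(fit)
  } else {
    abort("`fit` must be an `excess_line` or c(intercept, slope).")
  }
}

#' Monte Carlo threshold-classification simulation
#'
#' Propagates the two dominant uncertainties of cohort summary data through
#' the linear excess-mortality fit: per iteration, each cohort's mesothelioma
#' count is redrawn from a Poisson distribution and its cumulative exposure
#' from a uniform distribution spanning `1 +/- exposure_jitter` times the
#' reported value (expected total mortality is held at its point value).
#' Each redrawn table is refit by OLS ([fit_excess_line()]), classified with
#' [is_threshold_fit()], and the threshold `-A/B` is accumulated over the
#' threshold-classified iterations.
#'
#' `response_draw` selects the Poisson model for the response:
#'
#' * `"cases"` (default) — counts are Poisson about the observed case
#'   numbers and the published excess column is scaled by `M / M_observed`
#'   (cohorts with zero observed cases stay at zero). This treats the
#'   published excess rate as the authoritative level and the observed count
#'   as the source of Poisson variation, which keeps cohorts whose published
#'   excess disagrees with `cases/expected` (Connecticut) internally
#'   consistent.
#' * `"expected"` — counts are Poisson with mean
#'   `excess_rate * expected_mortality` and the response is recomputed as
#'   `100 * M / TM`.
#' * `"none"` — no Poisson noise; the response stays at the published
#'   excess. With `exposure_jitter = 0` every iteration collapses to the
#'   central fit.
#'
#' Iterations whose draw yields all-zero counts are retained; they fit
#' `A = B = 0` and count as non-threshold because `B > 0` fails.
#'
#' @param data A cohort table with at least three rows.
#' @param n_iter Number of Monte Carlo iterations.
#' @param exposure_jitter Half-width of the uniform multiplicative exposure
#'   error (default 0.30, i.e. 30% below to 30% above the reported value).
#' @param response_draw Poisson model for the response; see Details.
#' @param seed Integer seed for reproducibility.
#' @return An object of class `mc_threshold`; see [glance.mc_threshold()]
#'   for the summary statistics and [tidy.mc_threshold()] for the
#'   iteration-level draws.
#' @export
#' @examples
#' mc <- run_threshold_mc(cohort_table1(), n_iter = 500, seed = 1)
#' glance(mc)
run_threshold_mc <- function(data, n_iter = 10000, exposure_jitter = 0.30,
                             response_draw = c("cases", "expected", "none"),
                             seed = NULL) {
  data <- check_cohorts(data)
  response_draw <- match.arg(response_draw)
  if (nrow(data) < 3) abort("at least three cohorts are required.")
  if (n_iter < 1) abort("`n_iter` must be at least 1.")
  if (exposure_jitter < 0 || exposure_jitter >= 1) {
    abort("`exposure_jitter` must lie in [0, 1).")
  }
  k <- nrow(data)
  ce0 <- data$cumulative_fcc_years
  with_seed(seed, {
    ce <- matrix(
      runif(n_iter * k,
        rep(ce0, each = n_iter) * (1 - exposure_jitter),
        rep(ce0, each = n_iter) * (1 + exposure_jitter)
      ),
      nrow = n_iter
    )
    y <- switch(response_draw,
      cases = {
        m0 <- data$meso_cases
        scale <- ifelse(m0 > 0, 100 * data$excess_rate / pmax(m0, 1), 0)
        draws <- matrix(
          rpois(n_iter * k, rep(m0, each = n_iter)),
          nrow = n_iter
        )
        sweep(draws, 2, scale, `*`)
      },
      expected = {
        lam <- data$excess_rate * data$expected_mortality
        draws <- matrix(
          rpois(n_iter * k, rep(lam, each = n_iter)),
          nrow = n_iter
        )
        sweep(draws, 2, 100 / data$expected_mortality, `*`)
      },
      none = matrix(100 * data$excess_rate, n_iter, k, byrow = TRUE)
    )
    # row-wise simple OLS via the normal equations
    xbar <- rowMeans(ce)
    ybar <- rowMeans(y)
    sxx <- rowSums(ce^2) - k * xbar^2
    sxy <- rowSums(ce * y) - k * xbar * ybar
    ok <- sxx > 0
    if (!any(ok)) {
      abort("all Monte Carlo iterations had degenerate designs.")
    }
    slope <- ifelse(ok, sxy / sxx, NA_real_)
    intercept <- ybar - slope * xbar
    is_thr <- ok & intercept <= 0 & slope > 0
    thr <- ifelse(is_thr, -intercept / slope, NA_real_)
    draws <- tibble::tibble(
      iteration = seq_len(n_iter),
      intercept = intercept,
      slope = slope,
      threshold_relationship = is_thr,
      threshold = thr
    )
    tk <- thr[is_thr]
    n_thr <- length(tk)
    ci <- if (n_thr > 1) {
      mean(tk) + c(-1, 1) * 1.96 * sd(tk) / sqrt(n_thr)
    } else {
      c(NA_real_, NA_real_)
    }
    structure(
      list(
        draws = draws,
        fraction_threshold = mean(is_thr[ok]),
        mean_threshold = if (n_thr > 0) mean(tk) else NA_real_,
        ci_threshold = ci,
        p5 = if (n_thr > 0) unname(quantile(tk, 0.05)) else NA_real_,
        p95 = if (n_thr > 0) unname(quantile(tk, 0.95)) else NA_real_,
        mean_slope = mean(slope[ok]),
        mean_slope_threshold = if (n_thr > 0) {
          mean(slope[is_thr])
        } else {
          NA_real_
        },
        n_iter = n_iter,
        n_threshold = n_thr,
        exposure_jitter = exposure_jitter,
        response_draw = response_draw,
        seed = seed
      ),
      class = "mc_threshold"
    )
  })
}

#' @export
print.mc_threshold <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo threshold simulation (%d iterations, jitter +/-%d%%, response draw '%s')\n",
    x$n_iter, round(100 * x$exposure_jitter), x$response_draw
  ))
  cat(sprintf(
    "  threshold relationships: %.1f%% of fits\n",
    100 * x$fraction_threshold
  ))
  cat(sprintf(
    "  mean threshold: %.1f f/cc-years (95%% CI %.1f-%.1f; p5 %.1f, p95 %.1f)\n",
    x$mean_threshold, x$ci_threshold[1], x$ci_threshold[2], x$p5, x$p95
  ))
  cat(sprintf(
    "  mean slope: %.5f %%/f/cc-year (threshold fits: %.5f)\n",
    x$mean_slope, x$mean_slope_threshold
  ))
  invisible(x)
}

#' Iteration-level draws of a Monte Carlo threshold simulation
#'
#' @param x An `mc_threshold` object.
#' @param ... Unused.
#' @return A tibble with one row per iteration: `iteration`, `intercept`,
#'   `slope`, `threshold_relationship`, and `threshold` (`NA` for
#'   non-threshold fits).
#' @method tidy mc_threshold
#' @export
tidy.mc_threshold <- function(x, ...) {
  x$draws
}

#' Summary statistics of a Monte Carlo threshold simulation
#'
#' @param x An `mc_threshold` object.
#' @param ... Unused.
#' @return A one-row tibble: the fraction of threshold-classified fits, the
#'   mean threshold `-A/B` over those fits with its normal-approximation
#'   95% CI and 5th/95th percentiles (f/cc-years), the mean slope over all
#'   fits and over threshold fits (% per f/cc-year), and bookkeeping
#'   (`n_iter`, `n_threshold`, `seed`).
#' @method glance mc_threshold
#' @export
glance.mc_threshold <- function(x, ...) {
  tibble::tibble(
    fraction_threshold = x$fraction_threshold,
    mean_threshold = x$mean_threshold,
    ci_low = x$ci_threshold[1],
    ci_high = x$ci_threshold[2],
    p5 = x$p5,
    p95 = x$p95,
    mean_slope = x$mean_slope,
    mean_slope_threshold = x$mean_slope_threshold,
    n_iter = x$n_iter,
    n_threshold = x$n_threshold,
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed)
  )
}

#' Histogram of Monte Carlo threshold estimates
#'
#' @param object An `mc_threshold` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mc_threshold
#' @export
autoplot.mc_threshold <- function(object, bins = 40, ...) {
  dat <- dplyr::filter(object$draws, .data$threshold_relationship)
  ggplot2::ggplot(dat, ggplot2::aes(.data$threshold)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(
      xintercept = object$mean_threshold, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "Threshold -A/B (f/cc-years)", y = "Iterations",
      title = "Distribution of Monte Carlo threshold estimates",
      subtitle = sprintf(
        "%.0f%% of fits threshold-classified; mean %.1f f/cc-years",
        100 * object$fraction_threshold, object$mean_threshold
      )
    ) +
    ggplot2::theme_minimal()
}
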