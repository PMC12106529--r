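#' Fit the filter (quadratic-in-log-dose survival) model
#'
#' The filter model describes the survival-rate function S — the fraction
#' of a cohort's expected deaths not attributable to mesothelioma — as a
#' quadratic in log cumulative exposure:
#'
#'   S = c + a * ln(CE + 1) + b * ln(CE + 1)^2
#'
#' fitted by ordinary least squares. Its carcinogen threshold is the
#' inflection point of S as a function of CE, where the second derivative
#' changes sign (see [filter_threshold()]).
#'
#' The published survival column of a cohort table is rounded to three
#' decimals; by default the response is taken as `1 - excess_rate`, which
#' retains the full precision of the excess column (`s_source = "printed"`
#' uses the survival column as stored).
#'
#' @param data A cohort table (see [cohort-tables]) with at least four
#'   rows.
#' @param s_source `"unrounded"` (default) for `S = 1 - excess_rate`, or
#'   `"printed"` for the stored `survival` column.
#' @return An object of class `filter_fit` with coefficients `a`, `b`, `c`,
#'   `pearson_r`, `r_squared`, the Eq-style `threshold`
#'   `exp(1 - a/(2b))` (`NA` with a warning when `b = 0`), the analytic
#'   inflection exposure `exp(1 - a/(2b)) - 1`, and the per-cohort data.
#' @export
#' @examples
#' fit <- fit_filter(cohort_table1())
#' glance(fit)
fit_filter <- function(data, s_source = c("unrounded", "printed")) {
  data <- check_cohorts(data)
  s_source <- match.arg(s_source)
  if (nrow(data) < 4) abort("at least four cohorts are required.")
  s <- switch(s_source,
    unrounded = 1 - data$excess_rate,
    printed = data$survival
  )
  u <- log(data$cumulative_fcc_years + 1)
  fit <- tryCatch(
    lm(s ~ u + I(u^2)),
    error = function(e) abort(paste0("singular design: ", conditionMessage(e)))
  )
  co <- coef(fit)
  if (anyNA(co)) {
    abort("singular design: collinear log-dose terms.",
      class = "mesothresh_singular_error"
    )
  }
  a <- unname(co[["u"]])
  b <- unname(co[["I(u^2)"]])
  cc <- unname(co[["(Intercept)"]])
  if (abs(b) < 1e-12) {
    warn("quadratic coefficient b is (numerically) zero; threshold undefined.")
    b <- 0
    thr <- NA_real_
  } else {
    thr <- filter_threshold(a, b)
  }
  fitted_s <- cc + a * u + b * u^2
  structure(
    list(
      a = a, b = b, c = cc,
      threshold = thr,
      inflection = if (is.na(thr)) NA_real_ else thr - 1,
      pearson_r = if (sd(fitted_s) == 0 || sd(s) == 0) {
        NA_real_
      } else {
        stats::cor(fitted_s, s)
      },
      r_squared = {
        ss_tot <- sum((s - mean(s))^2)
        if (ss_tot == 0) NA_real_ else 1 - sum((s - fitted_s)^2) / ss_tot
      },
      s_source = s_source,
      data = tibble::tibble(
        name = data$name,
        cumulative_fcc_years = data$cumulative_fcc_years,
        log_dose = u,
        observed = s,
        fitted = fitted_s
      )
    ),
    class = "filter_fit"
  )
}

#' @export
print.filter_fit <- function(x, ...) {
  cat("Filter model: S = c + a ln(CE+1) + b ln(CE+1)^2\n")
  cat(sprintf(
    "  a = %.5g  b = %.5g  c = %.5g  (S source: %s)\n",
    x$a, x$b, x$c, x$s_source
  ))
  cat(sprintf(
    "  Pearson R = %.3f (R^2 = %.3f)\n", x$pearson_r, x$r_squared
  ))
  if (!is.na(x$threshold)) {
    cat(sprintf(
      "  threshold exp(1 - a/(2b)) = %.1f f/cc-years\n", x$threshold
    ))
  }
  invisible(x)
}

#' @export
tidy.filter_fit <- function(x, ...) {
  tibble::tibble(
    term = c("c", "a", "b"),
    estimate = c(x$c, x$a, x$b)
  )
}

#' @export
glance.filter_fit <- function(x, ...) {
  tibble::tibble(
    a = x$a, b = x$b, c = x$c,
    threshold = x$threshold,
    inflection = x$inflection,
    pearson_r = x$pearson_r,
    r_squared = x$r_squared,
    s_source = x$s_source,
    n = nrow(x$data)
  )
}

#' Survival curve and inflection point of a filter-model fit
#'
#' @param object A `filter_fit` object.
#' @param ... Unused.
#' @return A ggplot object showing the observed survival values, the fitted
#'   curve, and the inflection-point threshold.
#' @method autoplot filter_fit
#' @export
autoplot.filter_fit <- function(object, ...) {
  ce_max <- max(object$data$cumulative_fcc_years)
  grid <- tibble::tibble(
    cumulative_fcc_years = seq(0, ce_max, length.out = 200)
  )
  u <- log(grid$cumulative_fcc_years + 1)
  grid$fitted <- object$c + object$a * u + object$b * u^2
  p <- ggplot2::ggplot(
    object$data,
    ggplot2::aes(.data$cumulative_fcc_years, .data$observed)
  ) +
    ggplot2::geom_line(
      data = grid,
      ggplot2::aes(.data$cumulative_fcc_years, .data$fitted),
      colour = "steelblue"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Cumulative exposure (f/cc-years)",
      y = "Survival-rate function S",
      title = "Filter model fit",
      subtitle = sprintf(
        "threshold exp(1 - a/(2b)) = %.1f f/cc-years", object$threshold
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$threshold, linetype = "dashed", colour = "red"
    )
  }
  p
}

#' Filter-model threshold from the quadratic coefficients
#'
#' The threshold exposure at which the second derivative of the survival
#' function changes sign, in the form conventionally quoted for the filter
#' model:
#'
#'   CE_threshold = exp(1 - a / (2 b))
#'
#' (The exact root of `d^2 S / d CE^2` for the quadratic-in-`ln(CE+1)`
#' survival curve is `exp(1 - a/(2b)) - 1`; the two differ by less than 1%
#' at thresholds above ~100 f/cc-years. [filter_second_derivative()]
#' exposes the analytic root.)
#'
#' @param a Linear log-dose coefficient.
#' @param b Quadratic log-dose coefficient (nonzero).
#' @return Threshold in f/cc-years.
#' @export
#' @examples
#' filter_threshold(0.014, -0.00168) # ~175 from the rounded coefficients
filter_threshold <- function(a, b) {
  if (any(b == 0)) {
    abort("threshold is undefined when `b = 0`.",
      class = "mesothresh_contract_error"
    )
  }
  exp(1 - a / (2 * b))
}

#' Second derivative of the filter-model survival function
#'
#' For `S(CE) = c + a u + b u^2` with `u = ln(CE + 1)`,
#'
#'   d^2 S / d CE^2 = (2b - a - 2b * ln(CE + 1)) / (CE + 1)^2
#'
#' The sign change of this derivative — at `CE = exp(1 - a/(2b)) - 1` —
#' marks the inflection of the survival curve and hence the filter-model
#' threshold: below it the dose-response has no established downward trend,
#' above it the survival decline sets in.
#'
#' @param fit A `filter_fit` object, or a numeric `c(a, b)`.
#' @param ce Cumulative exposure(s), f/cc-years (>= 0).
#' @return The second derivative at `ce`, per (f/cc-years)^2.
#' @export
#' @examples
#' fit <- fit_filter(cohort_table1())
#' filter_second_derivative(fit, c(50, 200))
filter_second_derivative <- function(fit, ce) {
  if (inherits(fit, "filter_fit")) {
    a <- fit$a
    b <- fit$b
  } else if (is.numeric(fit) && length(fit) == 2) {
    a <- fit[[1]]
    b <- fit[[2]]
  } else {
    abort("`fit` must be a `filter_fit` or c(a, b).")
  }
  if (any(ce < 0)) abort("`ce` must be non-negative.")
  (2 * b - a - 2 * b * log(ce + 1)) / (ce + 1)^2
}

#' Single-anchor Monte Carlo threshold for a sparsely observed mineral
#'
#' When only one cohort datapoint is available for a mineral (the Libby
#' amphibole, LAA, case), the three filter-model coefficients cannot be
#' fitted. Instead, the single observation pins down one linear constraint,
#'
#'   anchor_s = c + a * u + b * u^2
#'
#' at the anchor log-dose `u` (the published anchor uses the constants
#' u = 2.77 and u^2 = 7.67). Drawing the baseline `c` and linear
#' coefficient `a` uniformly over the plausible ranges reported for the
#' filter model, solving for `b`, and evaluating
#' `threshold = exp(1 - a/(2b))` per draw yields a distribution of
#' thresholds. Draws with `|b|` below 1e-12 or thresholds above
#' `threshold_cap` (the heavy tail produced as b passes through zero) are
#' discarded and counted.
#'
#' @param anchor_s Survival value at the anchor point (default 0.97).
#' @param anchor_u Anchor log-dose `ln(CE + 1)` (default 2.77).
#' @param anchor_u2 Its square as used in the anchor identity
#'   (default 7.67).
#' @param c_range Uniform range for the baseline coefficient c.
#' @param a_range Uniform range for the linear coefficient a.
#' @param n_draws Number of Monte Carlo draws.
#' @param threshold_cap Discard draws with thresholds above this value,
#'   f/cc-years (default 100).
#' @param seed Integer seed.
#' @return An object of class `laa_sim` with `mean`, `sd`, `n_kept`,
#'   `n_discarded` and the kept draws.
#' @export
#' @examples
#' sim <- simulate_laa_anchor(n_draws = 2000, seed = 1)
#' glance(sim)
simulate_laa_anchor <- function(anchor_s = 0.97, anchor_u = 2.77,
                                anchor_u2 = 7.67,
                                c_range = c(0.9, 1),
                                a_range = c(-0.87, 1.3),
                                n_draws = 10000, threshold_cap = 100,
                                seed = NULL) {
  if (n_draws < 1) abort("`n_draws` must be at least 1.")
  if (diff(c_range) < 0 || diff(a_range) < 0) {
    abort("`c_range` and `a_range` must be non-decreasing ranges.")
  }
  with_seed(seed, {
    cc <- runif(n_draws, c_range[1], c_range[2])
    aa <- runif(n_draws, a_range[1], a_range[2])
    bb <- (anchor_s - cc - anchor_u * aa) / anchor_u2
    thr <- ifelse(abs(bb) > 1e-12, exp(1 - aa / (2 * bb)), NA_real_)
    keep <- !is.na(thr) & is.finite(thr) & thr <= threshold_cap
    if (!any(keep)) abort("all draws were discarded; widen the ranges.")
    draws <- tibble::tibble(
      c = cc[keep], a = aa[keep], b = bb[keep], threshold = thr[keep]
    )
    structure(
      list(
        mean = mean(draws$threshold),
        sd = sd(draws$threshold),
        n_kept = nrow(draws),
        n_discarded = n_draws - nrow(draws),
        threshold_cap = threshold_cap,
        draws = draws,
        seed = seed
      ),
      class = "laa_sim"
    )
  })
}

#' @export
print.laa_sim <- function(x, ...) {
  cat("Single-anchor filter-model threshold simulation\n")
  cat(sprintf(
    "  threshold: mean %.2f, sd %.2f f/cc-years (%d draws kept, %d discarded at cap %g)\n",
    x$mean, x$sd, x$n_kept, x$n_discarded, x$threshold_cap
  ))
  invisible(x)
}

#' @method tidy laa_sim
#' @export
tidy.laa_sim <- function(x, ...) {
  x$draws
}

#' @method glance laa_sim
#' @export
glance.laa_sim <- function(x, ...) {
  tibble::tibble(
    mean = x$mean, sd = x$sd,
    n_kept = x$n_kept, n_discarded = x$n_discarded,
    threshold_cap = x$threshold_cap,
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed)
  )
}

#' @export
autoplot.laa_sim <- function(object, bins = 40, ...) {
  ggplot2::ggplot(object$draws, ggplot2::aes(.data$threshold)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean, linetype = "dashed") +
    ggplot2::labs(
      x = "Threshold (f/cc-years)", y = "Draws",
      title = "Single-anchor threshold distribution",
      subtitle = sprintf("mean %.2f, sd %.2f", object$mean, object$sd)
    ) +
    ggplot2::theme_minimal()
}
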