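#' Parameters of the threshold-extended lifetime mesothelioma risk model
#'
#' The lifetime-risk model integrates the Peto-style age-response kernel
#' `K_M * E * (t - lag)^3` over the exposure window, giving the closed form
#'
#'   R(V, Y, D, E) = 1/4 * K_M * E * \[(V-Y-lag)^4 - (V-Y-lag-D)^4\]
#'
#' where V is lifespan, Y age at first exposure, D exposure duration
#' (years) and E average intensity (f/cc). The threshold extension replaces
#' the linear intensity term E by `E^power - threshold`, clamped at zero:
#' intensities with `E^power <= threshold` carry no excess risk. The
#' default parameters are the best-fit values for the built-in non-textile
#' chrysotile cohorts with `power = 1.5` and a 10-year lag.
#'
#' @param k_m Potency coefficient K_M (>= 0); default 0.0042e-8.
#' @param lifespan Lifespan V in years.
#' @param threshold Threshold Th in (f/cc)^power units (>= 0).
#' @param power Intensity exponent p (> 0), default 1.5.
#' @param lag Minimal latency in years, default 10.
#' @return An object of class `peto_params`.
#' @export
#' @examples
#' peto_params()
peto_params <- function(k_m = 0.0042e-8, lifespan = 85.9, threshold = 2.8,
                        power = 1.5, lag = 10) {
  if (k_m < 0) abort("`k_m` must be non-negative.")
  if (threshold < 0) abort("`threshold` must be non-negative.")
  if (power <= 0) abort("`power` must be positive.")
  if (lifespan <= lag) abort("`lifespan` must exceed `lag`.")
  structure(
    list(
      k_m = k_m, lifespan = lifespan, threshold = threshold,
      power = power, lag = lag
    ),
    class = "peto_params"
  )
}

#' @export
print.peto_params <- function(x, ...) {
  cat("Threshold-extended lifetime mesothelioma risk model\n")
  cat(sprintf(
    "  K_M = %g, V = %g y, Th = %g (f/cc)^%g, lag = %g y\n",
    x$k_m, x$lifespan, x$threshold, x$power, x$lag
  ))
  cat(sprintf(
    "  intensity threshold: %.3g f/cc\n",
    intensity_threshold(x$threshold, x$power)
  ))
  invisible(x)
}

#' Lifetime mesothelioma risk for an exposure scenario
#'
#' Evaluates the closed-form threshold-extended lifetime risk
#' `1/4 * K_M * max(0, E^p - Th) * [(V-Y-lag)^4 - max(0, V-Y-lag-D)^4]`.
#' Scenarios whose observation window closes before the lag elapses
#' (`Y + lag >= V`) have zero risk; negative risk increments (intensity
#' below threshold) are clamped to zero.
#'
#' @param params A [peto_params()] object.
#' @param intensity Average exposure intensity E, f/cc (>= 0); vectorised.
#' @param duration Exposure duration D, years (>= 0).
#' @param onset_age Age at first exposure Y, years (> 0).
#' @return Lifetime excess risk fraction(s), always >= 0.
#' @export
#' @examples
#' # Quebec miners: ~0.0055 vs the observed 0.0054
#' peto_risk(peto_params(), intensity = 17.14, duration = 35, onset_age = 23)
peto_risk <- function(params, intensity, duration, onset_age) {
  stopifnot(inherits(params, "peto_params"))
  if (any(intensity < 0) || any(duration < 0) || any(onset_age <= 0)) {
    abort("`intensity`, `duration` must be >= 0 and `onset_age` > 0.")
  }
  w <- pmax(0, params$lifespan - onset_age - params$lag)
  w_end <- pmax(0, w - duration)
  dose <- pmax(0, intensity^params$power - params$threshold)
  0.25 * params$k_m * dose * (w^4 - w_end^4)
}

#' Predicted lifetime risk for each cohort in a table
#'
#' @param data A cohort table (see [cohort-tables]).
#' @param params A [peto_params()] object.
#' @return `data` with an extra `.predicted` column of lifetime risks.
#' @export
#' @examples
#' peto_predict(cohort_table1(), peto_params())
peto_predict <- function(data, params) {
  data <- check_cohorts(data)
  dplyr::mutate(
    data,
    .predicted = peto_risk(
      params,
      intensity = .data$intensity_fcc,
      duration = .data$duration_years,
      onset_age = .data$onset_age
    )
  )
}

#' Fit the threshold-extended lifetime-risk model to a cohort table
#'
#' Minimises the sum of squared differences between predicted lifetime risk
#' and the observed excess-rate column over a grid of (lifespan, threshold)
#' pairs, with the potency coefficient K_M profiled analytically at each
#' grid point (risk is linear in K_M, so the conditionally optimal
#' `K_M = sum(g y) / sum(g^2)` is closed-form; it is clamped at zero to
#' keep potency non-negative). `power` and `lag` are fixed, not fitted.
#' The Pearson correlation between predictions and observations is reported
#' alongside because goodness of fit for this model is conventionally
#' quoted as R.
#'
#' Supplying `params` skips the fit and evaluates that fixed parameter set
#' against the table (useful for checking a published parameterisation).
#'
#' @param data A cohort table with at least four rows and non-constant
#'   `excess_rate`.
#' @param power Intensity exponent, fixed during the fit.
#' @param lag Minimal latency in years, fixed during the fit.
#' @param lifespan_grid Candidate lifespans V (years).
#' @param threshold_grid Candidate thresholds Th; defaults to
#'   `seq(0, min(intensity^power), by = 0.01)` so at least one cohort stays
#'   above threshold.
#' @param params Optional [peto_params()] object to evaluate without
#'   fitting.
#' @return An object of class `peto_fit`: the selected `peto_params`, the
#'   per-cohort predictions, `pearson_r`, `r_squared` and `sse`.
#' @export
#' @examples
#' fit <- fit_peto(cohort_table1())
#' glance(fit)
#' # evaluate the published parameter set instead of fitting
#' glance(fit_peto(cohort_table1(), params = peto_params()))
fit_peto <- function(data, power = 1.5, lag = 10,
                     lifespan_grid = seq(70, 100, by = 0.1),
                     threshold_grid = NULL, params = NULL) {
  data <- check_cohorts(data)
  y <- data$excess_rate
  if (is.null(params)) {
    if (nrow(data) < 4) abort("at least four cohorts are required to fit.")
    if (var(y) == 0) {
      abort("`excess_rate` must vary across cohorts to fit.")
    }
    if (is.null(threshold_grid)) {
      th_max <- min(data$intensity_fcc^power)
      threshold_grid <- seq(0, th_max, by = 0.01)
    }
    keep <- lifespan_grid > lag + min(data$onset_age)
    lifespan_grid <- lifespan_grid[keep]
    if (length(lifespan_grid) == 0 || length(threshold_grid) == 0) {
      abort("empty feasible parameter grid.")
    }
    # risk = K_M * W(V) * T(Th) per cohort: profile K_M on the outer grid
    w <- vapply(seq_len(nrow(data)), function(i) {
      win <- pmax(0, lifespan_grid - data$onset_age[i] - lag)
      0.25 * (win^4 - pmax(0, win - data$duration_years[i])^4)
    }, numeric(length(lifespan_grid))) # |V| x n
    tt <- vapply(
      data$intensity_fcc^power,
      function(ep) pmax(0, ep - threshold_grid),
      numeric(length(threshold_grid))
    ) # |Th| x n
    num <- (w %*% (y * t(tt)))^2 # (sum g y)^2, |V| x |Th|
    den <- w^2 %*% t(tt^2) # sum g^2
    obj <- ifelse(den > 0, num / den, 0) # explained sum of squares
    best <- arrayInd(which.max(obj), dim(obj))
    v_hat <- lifespan_grid[best[1]]
    th_hat <- threshold_grid[best[2]]
    g <- 0.25 * pmax(0, data$intensity_fcc^power - th_hat) *
      (pmax(0, v_hat - data$onset_age - lag)^4 -
        pmax(0, v_hat - data$onset_age - lag - data$duration_years)^4)
    k_hat <- max(0, sum(g * y) / sum(g^2))
    params <- peto_params(
      k_m = k_hat, lifespan = v_hat, threshold = th_hat,
      power = power, lag = lag
    )
    fitted_flag <- TRUE
  } else {
    stopifnot(inherits(params, "peto_params"))
    fitted_flag <- FALSE
  }
  pred <- peto_risk(
    params,
    intensity = data$intensity_fcc,
    duration = data$duration_years,
    onset_age = data$onset_age
  )
  structure(
    list(
      params = params,
      data = dplyr::mutate(
        data[c("name", "intensity_fcc", "duration_years", "onset_age")],
        observed = y, predicted = pred
      ),
      pearson_r = stats::cor(pred, y),
      r_squared = stats::cor(pred, y)^2,
      sse = sum((pred - y)^2),
      fitted = fitted_flag
    ),
    class = "peto_fit"
  )
}

#' @export
print.peto_fit <- function(x, ...) {
  cat(
    if (x$fitted) "Fitted" else "Evaluated",
    "threshold-extended lifetime-risk model\n"
  )
  print(x$params)
  cat(sprintf(
    "  Pearson R = %.4f (R^2 = %.3f), SSE = %.3g over %d cohorts\n",
    x$pearson_r, x$r_squared, x$sse, nrow(x$data)
  ))
  invisible(x)
}

#' @export
tidy.peto_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("k_m", "lifespan", "threshold", "power", "lag"),
    estimate = c(p$k_m, p$lifespan, p$threshold, p$power, p$lag),
    fitted = c(x$fitted, x$fitted, x$fitted, FALSE, FALSE)
  )
}

#' @export
glance.peto_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    k_m = p$k_m, lifespan = p$lifespan, threshold = p$threshold,
    power = p$power, lag = p$lag,
    intensity_threshold_fcc = intensity_threshold(p$threshold, p$power),
    pearson_r = x$pearson_r, r_squared = x$r_squared, sse = x$sse,
    n = nrow(x$data)
  )
}

#' Observed vs predicted excess mortality for a lifetime-risk fit
#'
#' @param object A `peto_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot peto_fit
#' @export
autoplot.peto_fit <- function(object, ...) {
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(.data$observed, .data$predicted, label = .data$name)
  ) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::labs(
      x = "Observed excess mesothelioma mortality",
      y = "Predicted lifetime risk",
      title = "Threshold-extended lifetime-risk model",
      subtitle = sprintf("Pearson R = %.3f", object$pearson_r)
    ) +
    ggplot2::theme_minimal()
}

#' Convert a model threshold to an exposure-intensity threshold
#'
#' The lifetime-risk model thresholds the transformed intensity `E^power`,
#' so the corresponding intensity threshold is `threshold^(1/power)`:
#' 2.8 at power 1.5 gives about 2 f/cc.
#'
#' @param threshold Model threshold Th in (f/cc)^power units (>= 0).
#' @param power Intensity exponent (> 0).
#' @return Intensity threshold in f/cc.
#' @export
#' @examples
#' intensity_threshold(2.8, 1.5) # ~2 f/cc
#' intensity_threshold(2.0, 1.8) # ~1.5 f/cc
intensity_threshold <- function(threshold, power) {
  if (any(threshold < 0)) abort("`threshold` must be non-negative.")
  if (any(power <= 0)) abort("`power` must be positive.")
  threshold^(1 / power)
}

#' Convert an intensity threshold to a cumulative-exposure threshold
#'
#' A worker exposed at the intensity threshold for an entire working life
#' of `max_duration` years accumulates `intensity * max_duration`
#' f/cc-years: 2 f/cc over 45 years gives 90 f/cc-years.
#'
#' @param intensity Intensity threshold, f/cc (>= 0).
#' @param max_duration Maximum plausible exposure duration, years (>= 0).
#' @return Cumulative-exposure threshold, f/cc-years.
#' @export
#' @examples
#' cumulative_threshold(2, 45) # 90
cumulative_threshold <- function(intensity, max_duration = 45) {
  if (any(intensity < 0) || any(max_duration < 0)) {
    abort("`intensity` and `max_duration` must be non-negative.")
  }
  intensity * max_duration
}
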