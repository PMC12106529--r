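#' Parameters of the conceptual three-factor excess-risk model
#'
#' The conceptual model expresses the probability of mesothelioma at
#' cumulative exposure X as the product of three counteracting exposure-
#' dependent processes:
#'
#'   P(X) = (lambda * X - 1) * (1 - beta * X) * alpha * X
#'
#' where `lambda * X - 1` tracks the probability that exposure triggers
#' chronic inflammation (a threshold process — negative below X = 1/lambda),
#' `1 - beta * X` the probability that pre-cancerous cells survive the
#' cytotoxic response, and `alpha * X` the probability of immunosuppression
#' or cell-immortalisation signalling. P is an excess-rate surrogate: it is
#' deliberately not clipped, and negative values mean "below baseline".
#' A positive-response window requires `lambda > beta`.
#'
#' @param lambda Inflammation rate parameter, per f/cc-year (> 0).
#' @param beta Cell-survival decay parameter, per f/cc-year (> 0).
#' @param alpha Immortalisation rate parameter, per f/cc-year (> 0).
#'   Defaults are the illustrative values used throughout the package.
#' @return An object of class `conceptual_params`.
#' @export
#' @examples
#' conceptual_params()
conceptual_params <- function(lambda = 0.0072, beta = 0.00125,
                              alpha = 0.000187) {
  if (lambda <= 0 || beta <= 0 || alpha <= 0) {
    abort("`lambda`, `beta` and `alpha` must all be positive.")
  }
  structure(
    list(lambda = lambda, beta = beta, alpha = alpha),
    class = "conceptual_params"
  )
}

#' @export
print.conceptual_params <- function(x, ...) {
  cat("Conceptual three-factor excess-risk model\n")
  cat(sprintf(
    "  lambda = %g, beta = %g, alpha = %g (per f/cc-year)\n",
    x$lambda, x$beta, x$alpha
  ))
  if (x$lambda > x$beta) {
    b <- conceptual_boundaries(x)
    cat(sprintf(
      "  positive response on (%.4g, %.4g) f/cc-years\n",
      b[["lower"]], b[["upper"]]
    ))
  }
  invisible(x)
}

#' Evaluate the conceptual excess-risk response
#'
#' @param params A [conceptual_params()] object.
#' @param x Cumulative exposure(s), f/cc-years (>= 0).
#' @return The excess-rate surrogate P(x), same length as `x`; may be
#'   negative (below baseline).
#' @export
#' @examples
#' conceptual_response(conceptual_params(), c(0, 100, 400))
conceptual_response <- function(params, x) {
  stopifnot(inherits(params, "conceptual_params"))
  if (any(x < 0)) abort("exposure `x` must be non-negative.")
  (params$lambda * x - 1) * (1 - params$beta * x) * (params$alpha * x)
}

#' Sign boundaries of the conceptual response
#'
#' The response is positive exactly on the open interval
#' `(1/lambda, 1/beta)`: below `1/lambda` inflammation is not triggered and
#' the modelled excess is negative (below baseline); above `1/beta` the
#' cytotoxic death rate dominates. The lower boundary is the model's
#' threshold exposure.
#'
#' @param params A [conceptual_params()] object with `lambda > beta`.
#' @return Named numeric vector `c(lower = 1/lambda, upper = 1/beta)`,
#'   f/cc-years.
#' @export
#' @examples
#' conceptual_boundaries(conceptual_params()) # c(138.9, 800)
conceptual_boundaries <- function(params) {
  stopifnot(inherits(params, "conceptual_params"))
  if (params$lambda <= params$beta) {
    abort("`lambda` must exceed `beta` for a positive-response window.")
  }
  c(lower = 1 / params$lambda, upper = 1 / params$beta)
}

#' Stationary points of the conceptual response
#'
#' Setting dP/dX = 0 gives the quadratic
#' `3 * beta * lambda * X^2 - 2 * (lambda + beta) * X + 1 = 0`
#' (alpha cancels). Its real roots, in ascending order, are the local
#' minimum inside the negative region and the local maximum of the
#' positive-response window — the exposure at which modelled excess risk
#' peaks before population mortality pulls it down.
#'
#' @param params A [conceptual_params()] object with `lambda > beta`.
#' @return Numeric vector of 0, 1 or 2 stationary exposures, f/cc-years,
#'   ascending; the last element (when present) is the local maximum.
#' @export
#' @examples
#' conceptual_stationary_points(conceptual_params()) # c(66.2, 559.8)
conceptual_stationary_points <- function(params) {
  stopifnot(inherits(params, "conceptual_params"))
  if (params$lambda <= params$beta) {
    abort("`lambda` must exceed `beta` for a positive-response window.")
  }
  a2 <- 3 * params$beta * params$lambda
  a1 <- -2 * (params$lambda + params$beta)
  a0 <- 1
  disc <- a1^2 - 4 * a2 * a0
  if (disc < 0) {
    return(numeric())
  }
  sort((-a1 + c(-1, 1) * sqrt(disc)) / (2 * a2))
}

#' Tabulate the conceptual model's four curves on an exposure grid
#'
#' Produces the response together with its three factors on a regular
#' exposure grid, in long format ready for plotting or CSV export.
#'
#' @param params A [conceptual_params()] object.
#' @param x_max Upper end of the exposure grid, f/cc-years.
#' @param n Number of grid points.
#' @return A tibble with columns `exposure`, `curve` (one of `response`,
#'   `inflammation`, `cell_survival`, `immortalization`) and `value`.
#' @export
#' @examples
#' conceptual_curve(conceptual_params(), x_max = 800, n = 5)
conceptual_curve <- function(params, x_max = 800, n = 201) {
  stopifnot(inherits(params, "conceptual_params"))
  if (x_max <= 0 || n < 2) abort("`x_max` must be positive and `n` >= 2.")
  x <- seq(0, x_max, length.out = n)
  wide <- tibble::tibble(
    exposure = x,
    response = conceptual_response(params, x),
    inflammation = params$lambda * x - 1,
    cell_survival = 1 - params$beta * x,
    immortalization = params$alpha * x
  )
  tidyr::pivot_longer(wide, -"exposure",
    names_to = "curve", values_to = "value"
  )
}

#' Plot the conceptual model curves
#'
#' @param object A [conceptual_params()] object.
#' @param x_max,n Grid controls passed to [conceptual_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot conceptual_params
#' @export
autoplot.conceptual_params <- function(object, x_max = 800, n = 201, ...) {
  dat <- conceptual_curve(object, x_max = x_max, n = n)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(.data$exposure, .data$value, colour = .data$curve)
  ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Cumulative exposure (f/cc-years)", y = NULL,
      title = "Conceptual three-factor mesothelioma threshold model"
    ) +
    ggplot2::theme_minimal()
}
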