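#' Mesothelioma potency ratios for asbestiform minerals
#'
#' Potency ratios relative to non-textile chrysotile, as used to rescale a
#' chrysotile threshold to other fibre types: crocidolite is more potent by
#' a factor of 364, amosite by 86, and Libby amphibole asbestos (LAA, a
#' tremolite surrogate) by 21. Where available, the absolute mesothelioma
#' potency R_M (percent excess mortality per f/cc-year) from meta-analysis
#' is carried alongside; the two routes (ratios vs absolute potencies) are
#' not perfectly consistent in the source literature, which is why the
#' table is data, not hard-coded behaviour.
#'
#' @return A tibble with columns `mineral`, `ratio` (relative to
#'   non-textile chrysotile, dimensionless > 0) and `potency_pct`
#'   (absolute R_M in percent, `NA` where not reported).
#' @export
#' @examples
#' potency_ratios()
potency_ratios <- function() {
  tibble::tibble(
    mineral = c(
      "non-textile chrysotile", "LAA", "amosite", "crocidolite",
      "fluoro-edenite"
    ),
    ratio = c(1, 21, 86, 364, NA),
    potency_pct = c(0.0011, NA, NA, 0.52, 0.12)
  )
}

#' Rescale a threshold by a relative potency ratio
#'
#' Under the proportionality assumption — no-observed-adverse-effect
#' levels scale inversely with mesothelioma potency — a mineral `ratio`
#' times more potent than the reference has a threshold `ratio` times
#' lower.
#'
#' @param reference_threshold Reference-mineral threshold, f/cc-years
#'   (> 0).
#' @param ratio Potency ratio of the target mineral relative to the
#'   reference (> 0).
#' @return Target-mineral threshold, f/cc-years.
#' @export
#' @examples
#' scale_by_potency_ratio(90, 21) # LAA: ~4.3 f/cc-years
#' scale_by_potency_ratio(90, 364) # crocidolite: ~0.25 f/cc-years
scale_by_potency_ratio <- function(reference_threshold, ratio) {
  if (any(reference_threshold <= 0) || any(ratio <= 0)) {
    abort("`reference_threshold` and `ratio` must be positive.")
  }
  reference_threshold / ratio
}

#' Rescale a threshold using absolute potencies
#'
#' Equivalent to [scale_by_potency_ratio()] with
#' `ratio = target_potency / reference_potency`: the target threshold is
#' `reference_threshold * reference_potency / target_potency`.
#'
#' @param reference_threshold Reference-mineral threshold, f/cc-years
#'   (> 0).
#' @param reference_potency Absolute potency R_M of the reference mineral,
#'   percent per f/cc-year (> 0).
#' @param target_potency Absolute potency of the target mineral (> 0).
#' @return Target-mineral threshold, f/cc-years.
#' @export
#' @examples
#' # crocidolite from absolute meta-analysis potencies
#' threshold_from_potency(90, 0.0011, 0.52)
threshold_from_potency <- function(reference_threshold, reference_potency,
                                   target_potency) {
  if (any(reference_threshold <= 0) || any(reference_potency <= 0) ||
    any(target_potency <= 0)) {
    abort("thresholds and potencies must be positive.")
  }
  reference_threshold * reference_potency / target_potency
}

#' Combine method-level threshold estimates into a central tendency
#'
#' Different dose-response models applied to the same mineral yield
#' different threshold estimates; their arithmetic mean serves as the
#' central-tendency threshold for that mineral.
#'
#' @param estimates A data frame with a numeric `value` column (threshold
#'   estimates in f/cc-years, all > 0) and optionally a `mineral` column,
#'   which must then be constant.
#' @return The arithmetic mean of `value`, f/cc-years.
#' @export
#' @examples
#' combine_central_tendency(
#'   tibble::tibble(
#'     mineral = "non-textile chrysotile",
#'     method = c("monte-carlo", "lifetime-risk", "filter"),
#'     value = c(25.6, 90, 162)
#'   )
#' )
combine_central_tendency <- function(estimates) {
  if (!is.data.frame(estimates) || !"value" %in% names(estimates)) {
    abort("`estimates` must be a data frame with a `value` column.")
  }
  if (nrow(estimates) == 0) abort("at least one estimate is required.")
  if (any(estimates$value <= 0)) abort("threshold estimates must be positive.")
  if ("mineral" %in% names(estimates) &&
    length(unique(estimates$mineral)) > 1) {
    abort("estimates for different minerals cannot be combined.")
  }
  mean(estimates$value)
}

#' Extrapolate a reference threshold across mineral types
#'
#' Applies [scale_by_potency_ratio()] to every mineral in a potency table.
#'
#' @param reference_threshold Threshold of the reference mineral
#'   (non-textile chrysotile), f/cc-years.
#' @param ratios A potency table as returned by [potency_ratios()];
#'   minerals with `NA` ratios are dropped.
#' @return A tibble with columns `mineral`, `ratio` and `threshold`
#'   (f/cc-years).
#' @export
#' @examples
#' extrapolate_thresholds(90)
extrapolate_thresholds <- function(reference_threshold = 90,
                                   ratios = potency_ratios()) {
  if (!all(c("mineral", "ratio") %in% names(ratios))) {
    abort("`ratios` must have `mineral` and `ratio` columns.")
  }
  ratios |>
    dplyr::filter(!is.na(.data$ratio)) |>
    dplyr::mutate(
      threshold = scale_by_potency_ratio(reference_threshold, .data$ratio)
    ) |>
    dplyr::select("mineral", "ratio", "threshold")
}
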