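#' Cohort summary tables
#'
#' A cohort table is an ordinary tibble with one row per occupational cohort
#' and nine columns describing its exposure and mesothelioma mortality
#' experience:
#'
#' * `name` — cohort label (unique).
#' * `duration_years` — average exposure duration, years.
#' * `intensity_fcc` — average exposure intensity, phase-contrast-microscopy
#'   (PCM) fibres per cubic centimetre (f/cc).
#' * `cumulative_fcc_years` — cumulative exposure, f/cc-years.
#' * `onset_age` — average age at first exposure, years.
#' * `meso_cases` — observed mesothelioma deaths.
#' * `expected_mortality` — total expected deaths from all causes (a measure
#'   of cohort size and age structure).
#' * `excess_rate` — excess mesothelioma mortality as a fraction of expected
#'   mortality.
#' * `survival` — survival-rate function S, the fraction of expected deaths
#'   not attributable to mesothelioma (S = 1 - excess_rate up to rounding).
#'
#' @name cohort-tables
NULL

cohort_columns <- c(
  "name", "duration_years", "intensity_fcc", "cumulative_fcc_years",
  "onset_age", "meso_cases", "expected_mortality", "excess_rate", "survival"
)

#' Built-in non-textile chrysotile cohort summaries
#'
#' Returns the six mining and general-industry (non-textile) chrysotile
#' cohorts used throughout the package: the Québec and Balangero miners and
#' millers, Quinghai miners, New Orleans asbestos-cement workers, Connecticut
#' friction-products workers, and the Russian (Asbest) miners and millers.
#' Values are stored exactly as published; `excess_rate` is the published
#' excess column, not recomputed from `meso_cases / expected_mortality`
#' (the two disagree for Connecticut — see [validate_cohorts()]).
#'
#' @return A tibble with 6 rows and the columns described in
#'   [cohort-tables].
#' @export
#' @examples
#' cohort_table1()
cohort_table1 <- function() {
  tibble::tibble(
    name = c(
      "Quebec miners and millers",
      "Balangero miners and millers",
      "Quinghai miners",
      "New Orleans asbestos cement workers",
      "Connecticut asbestos friction products workers",
      "Russian miners and millers"
    ),
    duration_years = c(35, 16.95, 27.3, 3.9, 8.04, 15),
    intensity_fcc = c(17.14, 42.5, 4.39, 5.64, 5.72, 2.24),
    cumulative_fcc_years = c(600, 721, 120, 22, 46, 33.6),
    onset_age = c(23, 27, 21.7, 27, 31, 24),
    meso_cases = c(33, 7, 0, 0, 2, 13),
    expected_mortality = c(5913, 549, 366, 500, 274, 10351),
    excess_rate = c(0.0054, 0.0128, 0, 0, 0.00072, 0.0012),
    survival = c(0.995, 0.987, 1, 1, 0.999, 0.998)
  )
}

check_cohorts <- function(data, call = rlang::caller_env()) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame of cohort summaries.", call = call)
  }
  missing <- setdiff(cohort_columns, names(data))
  if (length(missing) > 0) {
    abort(
      paste0(
        "cohort table is missing column(s): ",
        paste0("`", missing, "`", collapse = ", ")
      ),
      class = "mesothresh_schema_error", call = call
    )
  }
  if (nrow(data) == 0) {
    abort("cohort table must have at least one row.",
      class = "mesothresh_schema_error", call = call
    )
  }
  num <- setdiff(cohort_columns, "name")
  bad <- num[!vapply(data[num], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(
      paste0(
        "non-numeric cohort column(s): ",
        paste0("`", bad, "`", collapse = ", ")
      ),
      class = "mesothresh_schema_error", call = call
    )
  }
  if (anyDuplicated(data$name)) {
    abort("cohort names must be unique.",
      class = "mesothresh_validation_error", call = call
    )
  }
  checks <- list(
    duration_years = data$duration_years > 0,
    intensity_fcc = data$intensity_fcc >= 0,
    cumulative_fcc_years = data$cumulative_fcc_years >= 0,
    onset_age = data$onset_age > 0,
    meso_cases = data$meso_cases >= 0,
    expected_mortality = data$expected_mortality > 0,
    excess_rate = data$excess_rate >= 0 & data$excess_rate <= 1,
    survival = data$survival >= 0 & data$survival <= 1
  )
  for (col in names(checks)) {
    if (!all(checks[[col]], na.rm = FALSE)) {
      abort(
        paste0("invalid value(s) in cohort column `", col, "`."),
        class = "mesothresh_validation_error", call = call
      )
    }
  }
  if (any(data$meso_cases > data$expected_mortality)) {
    abort("`meso_cases` cannot exceed `expected_mortality`.",
      class = "mesothresh_validation_error", call = call
    )
  }
  invisible(tibble::as_tibble(data))
}

#' Read and write cohort summary tables
#'
#' Cohort tables are exchanged as plain UTF-8 CSV with a header row naming
#' the nine columns of [cohort-tables] (comma separator, decimal point).
#' `write_cohorts()` followed by `read_cohorts()` round-trips a table
#' field-for-field.
#'
#' @param path Path to a CSV file.
#' @param data A cohort table (see [cohort-tables]).
#' @return `read_cohorts()` returns a validated cohort tibble;
#'   `write_cohorts()` returns `data` invisibly.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_cohorts(cohort_table1(), path)
#' read_cohorts(path)
read_cohorts <- function(path) {
  # parsing problems are re-raised as typed errors below, so readr's own
  # warnings are silenced
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      name = readr::col_character(),
      .default = readr::col_double()
    )
  ))
  missing <- setdiff(cohort_columns, names(raw))
  if (length(missing) > 0) {
    abort(
      paste0(
        "CSV is missing required column(s): ",
        paste0("`", missing, "`", collapse = ", ")
      ),
      class = "mesothresh_schema_error"
    )
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(
      paste0(
        "could not parse cohort CSV: non-numeric value at row ",
        prob$row[1], ", column ", prob$col[1], "."
      ),
      class = "mesothresh_parse_error"
    )
  }
  check_cohorts(raw[cohort_columns])
}

#' @rdname read_cohorts
#' @export
write_cohorts <- function(data, path) {
  data <- check_cohorts(data)
  readr::write_csv(data[cohort_columns], path)
  invisible(data)
}

#' Cross-check internal consistency of a cohort table
#'
#' Runs three arithmetic cross-checks on each cohort and reports violations
#' as findings rather than errors, because published summary tables are kept
#' as printed:
#'
#' * cumulative exposure vs intensity times duration
#'   (relative tolerance `tol_ce`);
#' * survival vs `1 - excess_rate` (absolute tolerance 0.001);
#' * `meso_cases / expected_mortality` vs `excess_rate`
#'   (relative tolerance `tol_rate`; rows with both equal to zero pass).
#'
#' On the built-in table the third check flags the Connecticut cohort, whose
#' published excess rate (0.00072) is an order of magnitude below its
#' cases-over-expected ratio (2/274 = 0.0073).
#'
#' @param data A cohort table (see [cohort-tables]).
#' @param tol_ce Relative tolerance for the cumulative-exposure check,
#'   in (0, 1).
#' @param tol_rate Relative tolerance for the excess-rate check, in (0, 1).
#' @return A tibble of findings with columns `name`, `check`, `observed`,
#'   `expected`, `message`; zero rows when all checks pass.
#' @export
#' @examples
#' validate_cohorts(cohort_table1())
validate_cohorts <- function(data, tol_ce = 0.02, tol_rate = 0.10) {
  data <- check_cohorts(data)
  if (!(tol_ce > 0 && tol_ce < 1) || !(tol_rate > 0 && tol_rate < 1)) {
    abort("`tol_ce` and `tol_rate` must lie in (0, 1).")
  }
  finding <- function(name, check, observed, expected, message) {
    tibble::tibble(
      name = name, check = check, observed = observed,
      expected = expected, message = message
    )
  }
  out <- purrr::pmap(data, function(name, duration_years, intensity_fcc,
                                    cumulative_fcc_years, onset_age,
                                    meso_cases, expected_mortality,
                                    excess_rate, survival, ...) {
    rows <- list()
    prod <- intensity_fcc * duration_years
    if (cumulative_fcc_years > 0 &&
      abs(prod - cumulative_fcc_years) / cumulative_fcc_years > tol_ce) {
      rows <- c(rows, list(finding(
        name, "cumulative_exposure", cumulative_fcc_years, prod,
        sprintf(
          "cumulative exposure %g differs from intensity x duration = %g by more than %g%%",
          cumulative_fcc_years, prod, 100 * tol_ce
        )
      )))
    }
    if (abs(survival - (1 - excess_rate)) > 0.001) {
      rows <- c(rows, list(finding(
        name, "survival", survival, 1 - excess_rate,
        sprintf(
          "survival %g differs from 1 - excess_rate = %g by more than 0.001",
          survival, 1 - excess_rate
        )
      )))
    }
    ratio <- meso_cases / expected_mortality
    ok <- if (excess_rate == 0) {
      ratio == 0
    } else {
      abs(ratio - excess_rate) / excess_rate <= tol_rate
    }
    if (!ok) {
      rows <- c(rows, list(finding(
        name, "excess_rate", excess_rate, ratio,
        sprintf(
          "excess_rate %g differs from cases/expected = %g by more than %g%%",
          excess_rate, ratio, 100 * tol_rate
        )
      )))
    }
    rows
  })
  out <- purrr::list_flatten(out)
  if (length(out) == 0) {
    finding(character(), character(), numeric(), numeric(), character())
  } else {
    dplyr::bind_rows(out)
  }
}
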