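# small hand-built cohort table with exact linear structure for oracles:
# excess_rate = cases / tm exactly, cases = 0.1 * ce (integers by choice of ce)
toy_cohorts <- function(ce = c(10, 50, 100, 200), tm = 1000,
                        cases = round(0.1 * ce)) {
  n <- length(ce)
  excess <- cases / tm
  tibble::tibble(
    name = sprintf("toy-%d", seq_len(n)),
    duration_years = rep(10, n),
    intensity_fcc = ce / 10,
    cumulative_fcc_years = ce,
    onset_age = rep(25, n),
    meso_cases = cases,
    expected_mortality = rep(tm, n),
    excess_rate = excess,
    survival = 1 - excess
  )
}

# independent OLS oracle: explicit normal equations via solve()
ols_oracle <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}
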