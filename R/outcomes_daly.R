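# DALY computation: years of life lost (YLL) from deaths, years lived with
# disability (YLD) from hospital days, scaled to the cohort.

#' Years of life lost due to premature mortality
#'
#' Deaths multiplied by a constant loss function: the years lost per death
#' for the age group (11 years for adults aged 55-59 given a life
#' expectancy of 70; 66 years for children under four; 20 years under the
#' WHO-life-table sensitivity analysis).
#'
#' @param deaths Number of deaths (may be a cohort expectation).
#' @param years_lost_per_death Years lost per death; must be positive.
#' @return YLL in years.
#' @export
yll <- function(deaths, years_lost_per_death) {
  if (any(deaths < 0)) abort_validation("deaths must be nonnegative")
  if (any(years_lost_per_death <= 0)) {
    abort_validation("years_lost_per_death must be positive")
  }
  deaths * years_lost_per_death
}

#' Years lived with disability during hospitalisation
#'
#' Hospital days after diagnosis, converted to years and weighted by the
#' disability weight for a severe acute infectious episode (0.133 adults,
#' 0.402 under-fours).
#'
#' @param hospital_days Days in hospital after diagnosis.
#' @param disability_weight Dimensionless weight in \[0, 1\].
#' @param days_per_year Conversion constant, default 365.
#' @return YLD in years.
#' @export
yld <- function(hospital_days, disability_weight, days_per_year = 365) {
  if (any(hospital_days < 0) || any(disability_weight < 0)) {
    abort_validation("hospital_days and disability_weight must be nonnegative")
  }
  if (any(days_per_year <= 0)) abort_validation("days_per_year must be positive")
  hospital_days / days_per_year * disability_weight
}

#' DALY breakdown for a strategy result
#'
#' Scales a per-patient strategy result to the cohort and computes the DALY
#' decomposition: one DALY is one lost year of full health, the sum of YLL
#' and YLD.
#'
#' @param result A `labcea_result` from [rollback()].
#' @param daly_params The `daly` block of a parameter set
#'   (`years_lost_per_death`, `disability_weight`, `days_per_year`,
#'   `cohort_size`).
#' @return A one-row tibble: `arm`, `regimen`, `deaths`, `hospital_days`
#'   (cohort totals), `yll`, `yld`, `daly` (years).
#' @export
daly_breakdown <- function(result, daly_params) {
  n <- daly_params$cohort_size
  deaths <- result$expected_deaths_per_patient * n
  days <- result$expected_los_days_per_patient * n
  y_ll <- yll(deaths, daly_params$years_lost_per_death)
  y_ld <- yld(days, daly_params$disability_weight, daly_params$days_per_year)
  tibble(arm = result$arm, regimen = result$regimen,
         deaths = deaths, hospital_days = days,
         yll = y_ll, yld = y_ld, daly = y_ll + y_ld)
}
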