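#' Unit conventions for model time
#'
#' The amyloid-progression model is parameterised in months of age while the
#' pharmacokinetic and turnover models operate in hours.  A single fixed
#' conversion constant ties the two scales together: one month is taken as
#' 365.25 / 12 days, i.e. 730.5 hours.  Under this convention the reported
#' inflection time of the soluble-to-insoluble scaling function (7610 h)
#' corresponds to an age of about 10.4 months.
#'
#' @format `hours_per_month` is a single numeric value, 730.5.
#' @export
hours_per_month <- 24 * 365.25 / 12

#' Convert age in months to model time in hours
#'
#' Model time is measured from birth, so an animal's age maps directly onto
#' the time axis of the integrated turnover model.
#'
#' @param age_months Age in months; must be non-negative.
#' @return Time since birth in hours.
#' @seealso [hours_to_age()] for the inverse.
#' @examples
#' age_to_hours(1)      # 730.5
#' hours_to_age(7610)   # about 10.4 months
#' @export
age_to_hours <- function(age_months) {
  if (any(!is.finite(age_months)) || any(age_months < 0)) {
    stop("age_months must be finite and non-negative", call. = FALSE)
  }
  age_months * hours_per_month
}

#' Convert model time in hours to age in months
#'
#' @param hours Time since birth in hours; must be non-negative.
#' @return Age in months.
#' @export
hours_to_age <- function(hours) {
  if (any(!is.finite(hours)) || any(hours < 0)) {
    stop("hours must be finite and non-negative", call. = FALSE)
  }
  hours / hours_per_month
}

#' Convert age in weeks to months
#'
#' Study designs record the age at study start in weeks; the progression
#' model uses months.  One week is 7 days and one month 365.25/12 days.
#'
#' @param age_weeks Age in weeks.
#' @return Age in months.
#' @export
weeks_to_months <- function(age_weeks) {
  age_weeks * 7 / (365.25 / 12)
}
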