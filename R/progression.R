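## Logistic amyloid-progression model: age-dependent soluble/insoluble
## Abeta levels in drug-free Tg2576 animals.

#' Amyloid level at a given age
#'
#' Evaluates the logistic (Hill-type) amyloid-progression model
#' `baseline + (alpha - baseline) * age^p / (ec_i^p + age^p)`: flat at
#' `baseline` in young animals, an exponential-looking rise around the
#' inflection age `ec_i`, and a plateau at `alpha` in old animals.
#'
#' @param age_months Age(s) in months, non-negative.
#' @param params An [ap_params()] object.
#' @return Amyloid-beta level(s) in pg/mg.
#' @examples
#' ap_level(25, ap_params(variant = "sol_ab40"))
#' @export
ap_level <- function(age_months, params) {
  stopifnot(inherits(params, "ap_params"))
  if (any(!is.finite(age_months)) || any(age_months < 0)) {
    stop("age_months must be finite and non-negative", call. = FALSE)
  }
  r <- (age_months / params$ec_i)^params$p
  params$baseline + (params$alpha - params$baseline) * r / (1 + r)
}

#' Fold increase of amyloid level over the age range
#'
#' Ratio of the old-age plateau to the young-age level, e.g. about 141-fold
#' for soluble and 1330-fold for insoluble Abeta40 in Tg2576 mice.
#'
#' @param params An [ap_params()] object.
#' @param young_level Observed young-age level in pg/mg (defaults to the
#'   model baseline).
#' @return Unitless fold increase `alpha / young_level`.
#' @export
fold_increase <- function(params, young_level = params$baseline) {
  stopifnot(inherits(params, "ap_params"))
  if (!is.finite(young_level) || young_level <= 0) {
    stop("young_level must be positive", call. = FALSE)
  }
  params$alpha / young_level
}

#' Inflection age of the progression curve
#'
#' The age at which the level reaches the midpoint between baseline and
#' plateau (between 17 and 20 months for the Abeta variants in Tg2576 mice).
#'
#' @param params An [ap_params()] object.
#' @return Inflection age in months.
#' @export
inflection_age <- function(params) {
  stopifnot(inherits(params, "ap_params"))
  params$ec_i
}
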