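## Two-compartment first-order-absorption pharmacokinetics of MRK-560,
## evaluated in closed form by superposition over dose events.

# Macro (hybrid) rate constants of the two-compartment disposition model.
.pk_macro <- function(params) {
  k10 <- params$cl / params$v2
  k12 <- params$q / params$v2
  k21 <- params$q / params$v3
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  list(alpha = (s + disc) / 2, beta = (s - disc) / 2, k21 = k21)
}

#' Dose-, route- and vehicle-dependent bioavailability
#'
#' For oral dosing in vehicle 1 the bioavailability decreases with dose
#' following a saturable function `F(D) = theta2 + (1 - theta2) /
#' (1 + (theta1 * D)^theta3)`, which tends to 1 at vanishing dose and to
#' `theta2` at high dose.  Oral vehicles 2 and 3 and the subcutaneous route
#' use fixed fractions; intravenous dosing has bioavailability 1 by
#' definition.
#'
#' @param dose Dose in umol/kg (positive).
#' @param route `"oral"`, `"sc"` or `"iv"`.
#' @param vehicle Vehicle code 1, 2 or 3 (oral route only).
#' @param params A [pk_params()] object.
#' @param study_id Optional study id used to look up a study-specific
#'   `theta1` override.
#' @return Bioavailable fraction in (0, 1].
#' @export
bioavailability <- function(dose, route = c("oral", "sc", "iv"), vehicle = 1,
                            params = pk_params(), study_id = NULL) {
  route <- match.arg(route)
  if (any(dose <= 0)) stop("dose must be positive", call. = FALSE)
  if (route == "iv") return(rep(1, length(dose)))
  if (route == "sc") return(rep(params$f_sc, length(dose)))
  if (!vehicle %in% 1:3) {
    stop("unknown oral vehicle: ", vehicle, call. = FALSE)
  }
  if (vehicle == 2) return(rep(params$f_veh2, length(dose)))
  if (vehicle == 3) return(rep(params$f_veh3, length(dose)))
  th1 <- params$fdose_theta1
  if (!is.null(study_id) && length(params$theta1_by_study) &&
      !is.null(params$theta1_by_study[[as.character(study_id)]])) {
    th1 <- params$theta1_by_study[[as.character(study_id)]]
  }
  th2 <- params$fdose_theta2
  th2 + (1 - th2) / (1 + (th1 * dose)^params$fdose_theta3)
}

# Internal: per-dose table (time, F*amount, ka with ka <= 0 flagging iv bolus)
# used by both the R closed form and the compiled ODE right-hand side.
.dose_table <- function(doses, params, study_id = NULL) {
  if (is.null(doses) || !nrow(doses)) {
    return(data.frame(time_h = numeric(), amt_eff = numeric(), ka = numeric()))
  }
  f <- mapply(function(a, r, v) bioavailability(a, r, v, params, study_id),
              doses$amount, doses$route, doses$vehicle)
  ka <- ifelse(doses$route == "iv", -1,
               ifelse(doses$route == "sc", params$ka_sc, params$ka_po))
  data.frame(time_h = doses$time_h, amt_eff = f * doses$amount, ka = ka)
}

#' Plasma concentration of the two-compartment model
#'
#' Evaluates the closed-form solution of the two-compartment disposition
#' model with first-order absorption (oral/subcutaneous) or bolus input
#' (intravenous), superposed over all dose events and scaled by
#' bioavailability.  Concentration is right-continuous at dose instants: a
#' dose contributes from its own timestamp onwards.
#'
#' @param t_h Vector of times in hours (same clock as the dose times).
#' @param doses Data frame of dose events with columns `time_h`, `amount`
#'   (umol/kg), `route`, `vehicle`.
#' @param params A [pk_params()] object.
#' @param study_id Optional study id for the `theta1` bioavailability lookup.
#' @return Plasma concentration in umol/L at each time; 0 before the first
#'   dose.
#' @export
plasma_concentration <- function(t_h, doses, params = pk_params(),
                                 study_id = NULL) {
  dt <- .dose_table(doses, params, study_id)
  mac <- .pk_macro(params)
  cp <- numeric(length(t_h))
  if (!nrow(dt)) return(cp)
  a <- mac$alpha; b <- mac$beta; k21 <- mac$k21; v2 <- params$v2
  for (i in seq_len(nrow(dt))) {
    tau <- t_h - dt$time_h[i]
    on <- tau >= 0
    if (!any(on)) next
    tau <- tau[on]
    amt <- dt$amt_eff[i]
    ka <- dt$ka[i]
    if (ka <= 0) {  # iv bolus into the central compartment
      contr <- amt / v2 * ((a - k21) / (a - b) * exp(-a * tau) +
                             (k21 - b) / (a - b) * exp(-b * tau))
    } else {
      if (abs(ka - a) < 1e-10 || abs(ka - b) < 1e-10) {
        stop("absorption rate coincides with a disposition rate constant; ",
             "perturb the parameters", call. = FALSE)
      }
      contr <- amt * ka / v2 *
        ((k21 - a) / ((ka - a) * (b - a)) * exp(-a * tau) +
           (k21 - b) / ((ka - b) * (a - b)) * exp(-b * tau) +
           (k21 - ka) / ((a - ka) * (b - ka)) * exp(-ka * tau))
    }
    cp[on] <- cp[on] + contr
  }
  pmax(cp, 0)
}

#' Total brain concentration from plasma concentration
#'
#' The brain exposure model assumes instantaneous distribution of unbound
#' compound between plasma and brain, so total brain concentration is
#' proportional to plasma concentration with the estimated total
#' brain:plasma ratio as the constant of proportionality.
#'
#' @param cp Plasma concentration(s), umol/L.
#' @param params A [pk_params()] object.
#' @return Total brain concentration(s), umol/L.
#' @export
brain_concentration <- function(cp, params = pk_params()) {
  if (any(cp < 0)) stop("plasma concentration must be >= 0", call. = FALSE)
  params$brain_plasma_ratio * cp
}

#' Correct measured brain concentration for residual blood
#'
#' Brains are not perfused before exposure analysis, so a fixed fractional
#' blood volume (default 1.3%) carrying compound at the plasma concentration
#' contaminates the measured signal.  The corrected concentration is floored
#' at zero.
#'
#' @param brain_measured Measured total brain concentration, umol/L.
#' @param cp Paired plasma concentration, umol/L.
#' @param params A [pk_params()] object (uses `v_blood_brain`).
#' @return Blood-corrected brain concentration, umol/L.
#' @export
blood_contamination_correct <- function(brain_measured, cp,
                                        params = pk_params()) {
  if (any(brain_measured < 0) || any(cp < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  pmax(brain_measured - params$v_blood_brain * cp, 0)
}

#' Unbound concentration
#'
#' @param conc_total Total concentration, umol/L.
#' @param fu Unbound fraction in (0, 1] (e.g. `fu_pl` 0.004 or `fu_br`
#'   0.0067 for MRK-560).
#' @return Unbound concentration, umol/L.
#' @export
unbound_concentration <- function(conc_total, fu) {
  if (any(fu <= 0) || any(fu > 1)) stop("fu must lie in (0, 1]", call. = FALSE)
  conc_total * fu
}

#' Plasma and brain concentration profile
#'
#' Convenience wrapper evaluating the closed-form plasma concentration and
#' the corresponding total brain concentration on a time grid.
#'
#' @inheritParams plasma_concentration
#' @return A data frame of class `"pk_profile"` with columns `times_h`,
#'   `plasma_conc` and `brain_conc_total` (both umol/L).
#' @export
pk_profile <- function(t_h, doses, params = pk_params(), study_id = NULL) {
  cp <- plasma_concentration(t_h, doses, params, study_id)
  out <- data.frame(times_h = t_h, plasma_conc = cp,
                    brain_conc_total = brain_concentration(cp, params))
  class(out) <- c("pk_profile", "data.frame")
  out
}

#' @export
plot.pk_profile <- function(x, log = "y", ...) {
  pos <- x$plasma_conc > 0 | x$brain_conc_total > 0
  graphics::matplot(x$times_h[pos],
                    cbind(x$plasma_conc, x$brain_conc_total)[pos, , drop = FALSE],
                    type = "l", lty = c(1, 2), col = c("black", "grey40"),
                    xlab = "time (h)", ylab = "concentration (umol/L)",
                    log = if (all(c(x$plasma_conc, x$brain_conc_total) == 0)) "" else log,
                    ...)
  graphics::legend("topright", c("plasma", "brain (total)"),
                   lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  invisible(x)
}
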