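## Parameter containers.  Defaults are the published estimates for MRK-560
## pharmacokinetics and for amyloid progression / drug effect in Tg2576 mice.

#' Pharmacokinetic parameters for MRK-560
#'
#' Container for the two-compartment first-order-absorption model with
#' dose-, route- and vehicle-dependent bioavailability and the plasma-to-brain
#' exposure mapping.  Defaults are the reported population estimates for
#' MRK-560 in the mouse.
#'
#' @param ka_po Oral absorption rate constant, 1/h.
#' @param ka_sc Subcutaneous absorption rate constant, 1/h.
#' @param cl Clearance, L/h/kg.
#' @param v2 Central volume of distribution, L/kg.
#' @param q Inter-compartmental clearance, L/h/kg.
#' @param v3 Peripheral volume, L/kg.
#' @param brain_plasma_ratio Total brain:plasma concentration ratio (theta4),
#'   unitless; the partition coefficient of the instantaneous-equilibrium
#'   brain exposure model.
#' @param fu_pl,fu_br Unbound fractions in plasma and brain.
#' @param f_veh2,f_veh3,f_sc Bioavailability for oral vehicle 2, oral vehicle
#'   3 and the subcutaneous formulation.
#' @param fdose_theta1 Default study-level scale parameter of the
#'   dose-dependent oral (vehicle 1) bioavailability function; reported
#'   study-specific values range 0.0001-0.2.
#' @param fdose_theta2 High-dose asymptote of the oral vehicle-1
#'   bioavailability.
#' @param fdose_theta3 Shape parameter of the oral vehicle-1 bioavailability.
#' @param theta1_by_study Optional named list/vector of per-study overrides
#'   for `fdose_theta1`, keyed by study id.
#' @param bsv_omegas Named vector of log-normal between-subject SDs used for
#'   simulation only (approximate coefficients of variation); reported for
#'   `v2` (179%), `v3` (50%) and `brain_plasma_ratio` (61%).
#' @param v_blood_brain Fractional blood volume of brain tissue used for the
#'   blood-contamination correction of measured brain concentrations.
#' @return An object of class `"pk_params"`.
#' @export
pk_params <- function(ka_po = 0.41, ka_sc = 0.81, cl = 0.12, v2 = 0.28,
                      q = 7.6, v3 = 2.9, brain_plasma_ratio = 0.31,
                      fu_pl = 0.004, fu_br = 0.0067,
                      f_veh2 = 1, f_veh3 = 0.7, f_sc = 0.8,
                      fdose_theta1 = 0.01, fdose_theta2 = 0.22,
                      fdose_theta3 = 0.5, theta1_by_study = NULL,
                      bsv_omegas = c(v2 = 1.79, v3 = 0.50,
                                     brain_plasma_ratio = 0.61),
                      v_blood_brain = 0.013) {
  p <- list(ka_po = ka_po, ka_sc = ka_sc, cl = cl, v2 = v2, q = q, v3 = v3,
            brain_plasma_ratio = brain_plasma_ratio, fu_pl = fu_pl,
            fu_br = fu_br, f_veh2 = f_veh2, f_veh3 = f_veh3, f_sc = f_sc,
            fdose_theta1 = fdose_theta1, fdose_theta2 = fdose_theta2,
            fdose_theta3 = fdose_theta3,
            theta1_by_study = as.list(theta1_by_study),
            bsv_omegas = bsv_omegas, v_blood_brain = v_blood_brain)
  pos <- c("ka_po", "ka_sc", "cl", "v2", "q", "v3", "brain_plasma_ratio")
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop(nm, " must be a positive number", call. = FALSE)
    }
  }
  frac <- c("fu_pl", "fu_br", "f_veh2", "f_veh3", "f_sc", "fdose_theta2")
  for (nm in frac) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0 || p[[nm]] > 1) {
      stop(nm, " must lie in (0, 1]", call. = FALSE)
    }
  }
  if (p$fdose_theta1 <= 0 || p$fdose_theta3 <= 0) {
    stop("fdose_theta1 and fdose_theta3 must be positive", call. = FALSE)
  }
  structure(p, class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Two-compartment PK parameters (MRK-560):\n")
  cat(sprintf("  ka (oral) %.3g /h, ka (sc) %.3g /h, CL %.3g L/h/kg\n",
              x$ka_po, x$ka_sc, x$cl))
  cat(sprintf("  V2 %.3g L/kg, Q %.3g L/h/kg, V3 %.3g L/kg\n", x$v2, x$q, x$v3))
  cat(sprintf("  brain:plasma ratio %.3g, fu_pl %.3g, fu_br %.3g\n",
              x$brain_plasma_ratio, x$fu_pl, x$fu_br))
  cat(sprintf("  F: veh1 dose-dependent (theta1 %.4g, theta2 %.3g, theta3 %.3g), veh2 %.3g, veh3 %.3g, sc %.3g\n",
              x$fdose_theta1, x$fdose_theta2, x$fdose_theta3,
              x$f_veh2, x$f_veh3, x$f_sc))
  invisible(x)
}

#' Amyloid-progression parameters
#'
#' Parameters of the logistic age-progression model for one amyloid-beta
#' variant: `level(age) = baseline + (alpha - baseline) * age^p /
#' (ec_i^p + age^p)`.  With no arguments beyond `variant`, returns the
#' published estimates fitted to vehicle and untreated Tg2576 data.
#'
#' @param alpha Upper asymptote (plateau level in old animals), pg/mg.
#' @param ec_i Age at the inflection point (half-maximal rise), months.
#' @param p Slope (Hill) parameter, unitless.
#' @param baseline Young-age level, pg/mg; must be below `alpha`.
#' @param variant One of `"sol_ab40"`, `"insol_ab40"`, `"sol_ab42"`,
#'   `"insol_ab42"`.  When the numeric parameters are omitted they default to
#'   the published estimate for that variant.
#' @return An object of class `"ap_params"`.
#' @examples
#' ap_params(variant = "sol_ab40")                # published soluble-Abeta40 fit
#' ap_params(6620, 18.1, 7.5, 57.1, "sol_ab40")   # integrated-model re-fit
#' @export
ap_params <- function(alpha = NULL, ec_i = NULL, p = NULL, baseline = NULL,
                      variant = c("sol_ab40", "insol_ab40",
                                  "sol_ab42", "insol_ab42")) {
  variant <- match.arg(variant)
  defaults <- list(
    sol_ab40   = c(alpha = 6640,  ec_i = 20, p = 6.4, baseline = 48),
    insol_ab40 = c(alpha = 39900, ec_i = 17, p = 8.3, baseline = 29),
    sol_ab42   = c(alpha = 2240,  ec_i = 18, p = 5.9, baseline = 34),
    insol_ab42 = c(alpha = 40900, ec_i = 18, p = 6.8, baseline = 27)
  )[[variant]]
  if (is.null(alpha)) alpha <- defaults[["alpha"]]
  if (is.null(ec_i)) ec_i <- defaults[["ec_i"]]
  if (is.null(p)) p <- defaults[["p"]]
  if (is.null(baseline)) baseline <- defaults[["baseline"]]
  if (!is.finite(alpha) || !is.finite(baseline) || alpha <= baseline ||
      baseline <= 0) {
    stop("require alpha > baseline > 0", call. = FALSE)
  }
  if (!is.finite(ec_i) || ec_i <= 0) stop("ec_i must be positive", call. = FALSE)
  if (!is.finite(p) || p <= 0) stop("p must be positive", call. = FALSE)
  structure(list(alpha = alpha, ec_i = ec_i, p = p, baseline = baseline,
                 variant = variant),
            class = "ap_params")
}

#' @export
print.ap_params <- function(x, ...) {
  cat(sprintf("Amyloid progression (%s): alpha %.4g pg/mg, EC_i %.3g months, P %.3g, baseline %.3g pg/mg\n",
              x$variant, x$alpha, x$ec_i, x$p, x$baseline))
  invisible(x)
}

#' Pharmacodynamic parameters of the integrated turnover model
#'
#' Parameters of the coupled soluble/insoluble Abeta40 turnover model with
#' age-driven production and drug inhibition.  Defaults are the published
#' final (model C) estimates; models A and B take configurable parameters
#' through the same container.
#'
#' @param kout_sol Soluble Abeta40 turnover rate, 1/h (fixed at 1.1/h in the
#'   published analysis, a 38-min half-life).
#' @param imax For models B and C the maximal fractional inhibition of
#'   soluble-Abeta40 production (in (0, 1]); for model A the absolute maximal
#'   production decrement, pg/mg/h.
#' @param sl Slope of the linear relationship between the soluble Abeta40
#'   level and the IC50 (model C): `IC50 = a_sol / sl`, so `sl` carries units
#'   (pg/mg) per (umol/L).
#' @param ic50_fixed Fixed IC50, umol/L (models A and B).
#' @param kout_insol Insoluble Abeta40 turnover rate, 1/h (0.001/h, about a
#'   30-day half-life).
#' @param baseline_insol Young-age insoluble Abeta40 level, pg/mg.
#' @param alpha2 Upper asymptote of the soluble-to-insoluble scaling
#'   function, unitless ratio.
#' @param ec_i2 Inflection time of the scaling function, hours since birth.
#' @param p2 Slope parameter of the scaling function.
#' @param effect_model `"A"`, `"B"` or `"C"`.
#' @param ap An [ap_params()] object for soluble Abeta40; its `baseline`
#'   doubles as the soluble baseline of the integrated model.
#' @param drive_unbound If `TRUE`, inhibition is driven by unbound rather
#'   than total brain concentration (requires `fu_br` in the PK parameters);
#'   the default uses total brain concentration, consistent with IC50 values
#'   quoted on the total scale.
#' @return An object of class `"pd_params"`.
#' @export
pd_params <- function(kout_sol = 1.1, imax = 0.86, sl = 514,
                      ic50_fixed = NULL, kout_insol = 0.001,
                      baseline_insol = 28.9, alpha2 = 6.5, ec_i2 = 7610,
                      p2 = 9.1, effect_model = c("C", "A", "B"),
                      ap = ap_params(6620, 18.1, 7.5, 57.1, "sol_ab40"),
                      drive_unbound = FALSE) {
  effect_model <- match.arg(effect_model)
  stopifnot(inherits(ap, "ap_params"))
  if (!is.finite(kout_sol) || kout_sol <= 0) stop("kout_sol must be > 0", call. = FALSE)
  if (!is.finite(kout_insol) || kout_insol <= 0) stop("kout_insol must be > 0", call. = FALSE)
  if (!is.finite(alpha2) || alpha2 <= 0) stop("alpha2 must be > 0", call. = FALSE)
  if (!is.finite(ec_i2) || ec_i2 <= 0 || !is.finite(p2) || p2 <= 0) {
    stop("ec_i2 and p2 must be > 0", call. = FALSE)
  }
  if (effect_model %in% c("B", "C")) {
    if (!is.finite(imax) || imax <= 0 || imax > 1) {
      stop("imax must lie in (0, 1] for models B and C", call. = FALSE)
    }
  } else if (!is.finite(imax) || imax <= 0) {
    stop("imax (absolute maximal effect) must be > 0 for model A", call. = FALSE)
  }
  if (effect_model == "C") {
    if (is.null(sl) || !is.finite(sl) || sl <= 0) {
      stop("model C requires a positive IC50 slope `sl`", call. = FALSE)
    }
  } else {
    if (is.null(ic50_fixed) || !is.finite(ic50_fixed) || ic50_fixed <= 0) {
      stop("models A and B require a positive `ic50_fixed`", call. = FALSE)
    }
  }
  if (baseline_insol < 0) stop("baseline_insol must be >= 0", call. = FALSE)
  structure(list(kout_sol = kout_sol, imax = imax, sl = sl,
                 ic50_fixed = ic50_fixed, baseline_sol = ap$baseline,
                 kout_insol = kout_insol, baseline_insol = baseline_insol,
                 alpha2 = alpha2, ec_i2 = ec_i2, p2 = p2,
                 effect_model = effect_model, ap = ap,
                 drive_unbound = isTRUE(drive_unbound)),
            class = "pd_params")
}

#' @export
print.pd_params <- function(x, ...) {
  cat(sprintf("Integrated turnover model, drug-effect model %s\n", x$effect_model))
  cat(sprintf("  soluble:   kout %.3g /h (t1/2 %.1f min), baseline %.3g pg/mg\n",
              x$kout_sol, log(2) / x$kout_sol * 60, x$baseline_sol))
  if (x$effect_model == "C") {
    cat(sprintf("  drug:      Imax %.3g, IC50 slope %.4g (IC50 = a_sol / SL)\n",
                x$imax, x$sl))
  } else if (x$effect_model == "B") {
    cat(sprintf("  drug:      Imax %.3g, IC50 %.3g umol/L\n", x$imax, x$ic50_fixed))
  } else {
    cat(sprintf("  drug:      Eabs %.3g pg/mg/h, IC50 %.3g umol/L\n",
                x$imax, x$ic50_fixed))
  }
  cat(sprintf("  insoluble: kout %.3g /h (t1/2 %.1f days), baseline %.3g pg/mg\n",
              x$kout_insol, log(2) / x$kout_insol / 24, x$baseline_insol))
  cat(sprintf("  scaling:   alpha2 %.3g, EC_i2 %.4g h, P2 %.3g\n",
              x$alpha2, x$ec_i2, x$p2))
  print(x$ap)
  invisible(x)
}
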