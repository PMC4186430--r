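## Synthetic study generator: cross-sectional age series and in-house-style
## MRK-560 study designs, with residual and between-subject noise, so every
## stage of the analysis is testable without external data.

#' Study design specification
#'
#' Describes one preclinical study arm layout: strain, age at start, group
#' sizes, treatment duration, daily doses, route/vehicle and the sampling
#' times after the last dose.  When several sampling times are given the
#' animals of each arm are split across sampling-time cohorts (terminal
#' sampling is destructive).
#'
#' @param study_id Study identifier.
#' @param strain `"C57BL/6"`, `"Tg2576"` or `"littermate"`.
#' @param age_start_weeks Length-1 or length-2 (range) age at study start in
#'   weeks; ranges are sampled uniformly per animal.
#' @param n_treated,n_vehicle Group sizes (treated total across dose levels).
#' @param treatment_days Number of once-daily dosing days.
#' @param daily_doses Vector of dose levels, umol/kg.
#' @param route,vehicle Route of administration and (oral) vehicle code.
#' @param sample_times_post_dose_h Sampling times in hours after the last
#'   dose.
#' @param endpoints Endpoints measured; defaults to soluble and insoluble
#'   Abeta40 for Tg2576 and to drug concentrations otherwise.
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(study_id, strain, age_start_weeks, n_treated,
                         n_vehicle, treatment_days, daily_doses,
                         route = "oral", vehicle = 1,
                         sample_times_post_dose_h = 3,
                         endpoints = NULL) {
  route <- .normalize_route(route)
  if (n_treated < 1) stop("n_treated must be >= 1", call. = FALSE)
  if (n_vehicle < 0) stop("n_vehicle must be >= 0", call. = FALSE)
  if (any(daily_doses <= 0)) stop("doses must be positive", call. = FALSE)
  if (any(sample_times_post_dose_h < 0)) {
    stop("sample times must be >= 0", call. = FALSE)
  }
  if (treatment_days < 1) stop("treatment_days must be >= 1", call. = FALSE)
  if (is.null(endpoints)) {
    endpoints <- if (strain == "Tg2576") c("sol_ab40", "insol_ab40")
    else c("plasma_conc", "brain_conc_total")
  }
  structure(list(study_id = as.character(study_id), strain = strain,
                 age_start_weeks = range(age_start_weeks),
                 n_treated = as.integer(n_treated),
                 n_vehicle = as.integer(n_vehicle),
                 treatment_days = as.integer(treatment_days),
                 daily_doses = daily_doses, route = route,
                 vehicle = as.integer(vehicle),
                 sample_times_post_dose_h = sample_times_post_dose_h,
                 endpoints = endpoints),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study %s: %s, start %s weeks, %d treated + %d vehicle\n",
              x$study_id, x$strain,
              paste(unique(x$age_start_weeks), collapse = "-"),
              x$n_treated, x$n_vehicle))
  cat(sprintf("  %d day(s) daily %s dosing (vehicle %d): %s umol/kg; sampling %s h post dose\n",
              x$treatment_days, x$route, x$vehicle,
              paste(x$daily_doses, collapse = ", "),
              paste(x$sample_times_post_dose_h, collapse = ", ")))
  invisible(x)
}

#' The 23 in-house MRK-560 study designs
#'
#' Machine-readable transcription of the published summary of the 23
#' in-house MRK-560 study designs (species, age at start, group sizes,
#' treatment duration, sampling times, doses, route and vehicle).  Two
#' PK-only studies have no recorded start age; a nominal adult age of 12
#' weeks is used.  The single-dose oral/intravenous PK study is encoded with
#' its oral arm.  Studies run in mixed Tg2576/littermate cohorts are encoded
#' as Tg2576, the strain carrying the efficacy readout.
#'
#' @return A named list of 23 [study_design()] objects.
#' @export
table1_designs <- function() {
  d <- list(
    study_design(1, "C57BL/6", 10, 9, 9, 7, 30, "oral", 1, c(4.5, 172.5)),
    study_design(2, "C57BL/6", 14, 6, 3, 4, c(7.5, 30), "sc", 2, 3),
    study_design(3, "C57BL/6", 15, 12, 6, 4, c(7.5, 30), "sc", 2, 3),
    study_design(4, "C57BL/6", 12, 3, 0, 1, 10, "sc", 2,
                 c(0.5, 1.5, 3, 5, 7, 24)),
    study_design(5, "C57BL/6", 12, 6, 0, 1, c(3, 10), "oral", 1,
                 c(0.016, 0.08, 0.36, 0.66, 1, 3, 6, 24, 48)),
    study_design(6, "littermate", 28, 15, 10, 28, 30, "oral", 1, 4.5),
    study_design(7, "Tg2576", 20, 10, 10, 4, 70, "oral", 1, 3),
    study_design(8, "Tg2576", 24, 30, 15, 30, c(0.5, 6), "oral", 1, 3),
    study_design(9, "Tg2576", 24, 30, 15, 94, c(0.5, 6), "oral", 1, 3),
    study_design(10, "Tg2576", 24, 74, 30, 29, c(1, 3, 6), "oral", 1, 3),
    study_design(11, "Tg2576", 24, 16, 16, 30, 6, "oral", 1, 3),
    study_design(12, "Tg2576", 25, 6, 6, 1, 70, "oral", 1, 3),
    study_design(13, "Tg2576", 25, 24, 6, 4, c(1, 3, 7.5), "oral", 1, 3),
    study_design(14, "Tg2576", 25, 30, 30, 1, 70, "oral", 1,
                 c(3, 6, 24, 48, 120)),
    study_design(15, "Tg2576", 36, 20, 20, 8, 6, "oral", 3, 3),
    study_design(16, "Tg2576", 60, 27, 27, 4, 6, "oral", 1, 3),
    study_design(17, "Tg2576", 68, 11, 10, 4, 6, "oral", 1, 3),
    study_design(18, "Tg2576", c(81, 89), 80, 80, 1, 70, "oral", 1,
                 c(6, 24, 48, 96)),
    study_design(19, "Tg2576", 32, 12, 12, 4, 30, "oral", 1, 4.5),
    study_design(20, "Tg2576", 32, 12, 8, 21, 30, "oral", 1, 4.5),
    study_design(21, "Tg2576", 36, 30, 30, 8, 6, "oral", 3, 3),
    study_design(22, "Tg2576", c(24, 28), 34, 12, 45, 30, "oral", 1, 4.5),
    study_design(23, "Tg2576", c(37, 40), 16, 16, 28, 30, "oral", 1, 4.5)
  )
  stats::setNames(d, vapply(d, function(x) x$study_id, character(1)))
}

#' Noise specification for synthetic data
#'
#' @param residual Named list of [error_model()] objects keyed by endpoint;
#'   endpoints without an entry are generated noise-free.  Defaults to the
#'   published residual CVs for soluble (51%) and insoluble (83%) Abeta40
#'   and a 20% assay CV for drug concentrations.
#' @param pk_bsv Named vector of log-normal between-subject SDs applied to
#'   PK parameters per animal (reported for `v2`, `v3` and
#'   `brain_plasma_ratio`); use `NULL` or zeros for no between-subject
#'   variability.
#' @param seed Default seed recorded in the specification and used by the
#'   generators unless overridden.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(residual = list(
                         sol_ab40 = error_model("proportional", 0.51),
                         insol_ab40 = error_model("proportional", 0.83),
                         plasma_conc = error_model("proportional", 0.20),
                         brain_conc_total = error_model("proportional", 0.20)),
                       pk_bsv = c(v2 = 1.79, v3 = 0.50,
                                  brain_plasma_ratio = 0.61),
                       seed = 1L) {
  if (!is.null(residual)) {
    stopifnot(all(vapply(residual, inherits, TRUE, "error_model")))
    stopifnot(all(names(residual) %in% .endpoints))
  }
  structure(list(residual = residual, pk_bsv = pk_bsv, seed = as.integer(seed)),
            class = "noise_spec")
}

# One noisy draw per element of `mean` under an error model (NULL = exact).
# Proportional noise is realised as a mean-matched log-normal so that
# observations stay positive even at high CV.
.draw_noise <- function(mean, em) {
  if (is.null(em)) return(mean)
  if (em$kind == "additive") {
    return(pmax(mean + stats::rnorm(length(mean), 0, em$sd), .Machine$double.eps))
  }
  sdlog <- if (em$kind == "proportional") sqrt(log1p(em$sd^2)) else em$sd
  meanlog <- if (em$kind == "proportional") log(mean) - sdlog^2 / 2 else log(mean)
  stats::rlnorm(length(mean), meanlog, sdlog)
}

#' Generate cross-sectional drug-free amyloid data
#'
#' Emulates the cross-sectional design of the drug-free analysis: one
#' terminal observation per animal per requested Abeta variant, with the
#' mean given by the progression curve at the animal's age and noise drawn
#' from the residual error model.
#'
#' @param n_animals Number of animals.
#' @param age_range_months Length-2 vector; ages are drawn uniformly over
#'   this range unless `ages` is given.
#' @param ap An [ap_params()] object or a list of them (one per variant).
#' @param noise A [noise_spec()]; only the residual components matter here.
#' @param ages Optional explicit vector of ages (recycled to `n_animals`).
#' @param seed Seed; defaults to `noise$seed`.
#' @param study_id,arm Covariates stamped on the generated animals.
#' @param pd,pk Optional: when a [pd_params()] object is supplied, the
#'   drug-free means for soluble and insoluble Abeta40 are taken from the
#'   integrated turnover model (one ODE solve) instead of the standalone
#'   progression curves, so that cross-sectional data are internally
#'   consistent with datasets generated by [generate_study()].
#' @return An [as_dataset()] object with one animal record and one
#'   observation per animal and variant (termination at `time_h = 0`).
#' @export
generate_cross_sectional <- function(n_animals, age_range_months = c(3.5, 26),
                                     ap = ap_params(variant = "sol_ab40"),
                                     noise = noise_spec(), ages = NULL,
                                     seed = noise$seed, study_id = "xsec",
                                     arm = "naive", pd = NULL,
                                     pk = pk_params()) {
  stopifnot(inherits(noise, "noise_spec"))
  if (inherits(ap, "ap_params")) ap <- list(ap)
  stopifnot(all(vapply(ap, inherits, TRUE, "ap_params")))
  if (is.null(ages)) {
    if (length(age_range_months) != 2 || diff(age_range_months) <= 0 ||
        age_range_months[1] <= 0 || age_range_months[2] > 30) {
      stop("age_range_months must be an increasing range within (0, 30]",
           call. = FALSE)
    }
  }
  withr_seed(seed, {
    if (is.null(ages)) {
      ages <- stats::runif(n_animals, age_range_months[1], age_range_months[2])
    } else {
      ages <- rep_len(ages, n_animals)
    }
    ids <- sprintf("%s-%04d", study_id, seq_len(n_animals))
    animals <- data.frame(animal_id = ids, strain = "Tg2576",
                          age_at_start_months = ages, study_id = study_id,
                          arm = arm)
    if (is.null(pd)) {
      obs <- do.call(rbind, lapply(ap, function(a) {
        mu <- ap_level(ages, a)
        data.frame(animal_id = ids, time_h = 0, endpoint = a$variant,
                   value = .draw_noise(mu, noise$residual[[a$variant]]),
                   blq_flag = FALSE, lloq = NA_real_)
      }))
    } else {
      stopifnot(inherits(pd, "pd_params"))
      tt <- age_to_hours(ages)
      sol <- .pkpd_solve(tt, data.frame(time_h = numeric(),
                                        amt_eff = numeric(), ka = numeric()),
                         pk, pd)
      k <- match(tt, sol[, "time"])
      obs <- do.call(rbind, lapply(c("sol_ab40", "insol_ab40"), function(ep) {
        mu <- if (ep == "sol_ab40") sol[k, "a_sol"] else sol[k, "a_insol"]
        data.frame(animal_id = ids, time_h = 0, endpoint = ep,
                   value = .draw_noise(mu, noise$residual[[ep]]),
                   blq_flag = FALSE, lloq = NA_real_)
      }))
    }
    as_dataset(animals, NULL, obs)
  })
}

# Draw per-animal PK parameters with log-normal between-subject factors.
.draw_pk <- function(pk, bsv) {
  if (is.null(bsv) || !length(bsv) || all(bsv == 0)) return(pk)
  for (nm in names(bsv)) {
    if (bsv[[nm]] > 0) pk[[nm]] <- pk[[nm]] * exp(stats::rnorm(1, 0, bsv[[nm]]))
  }
  pk
}

#' Generate a synthetic MRK-560-style study
#'
#' Simulates one study design: per-animal ages (uniform over the stated
#' start range), once-daily dosing, terminal sampling by cohort, the
#' integrated turnover model for amyloid endpoints and the closed-form PK
#' for drug concentrations, with between-subject PK variability and
#' residual noise per the noise specification.  Vehicle-arm animals get a
#' drug-free simulation.
#'
#' @param spec A [study_design()] object.
#' @param pk,pd [pk_params()] and [pd_params()] objects (generating truth).
#' @param noise A [noise_spec()].
#' @param seed Seed; defaults to `noise$seed`.
#' @return An [as_dataset()] object with dose events for treated animals and
#'   terminal observations for all animals.
#' @export
generate_study <- function(spec, pk = pk_params(), pd = pd_params(),
                           noise = noise_spec(), seed = noise$seed) {
  stopifnot(inherits(spec, "study_design"), inherits(noise, "noise_spec"))
  withr_seed(seed, {
    n_tr <- spec$n_treated
    n_ve <- spec$n_vehicle
    n <- n_tr + n_ve
    ages_w <- stats::runif(n, spec$age_start_weeks[1], spec$age_start_weeks[2])
    ages_m <- weeks_to_months(ages_w)
    ids <- sprintf("s%s-%03d", spec$study_id, seq_len(n))
    arm <- c(rep("treated", n_tr), rep("vehicle", n_ve))
    dose_lvl <- c(rep_len(spec$daily_doses, n_tr), rep(NA_real_, n_ve))
    samp <- rep_len(spec$sample_times_post_dose_h, n)  # cohort allocation

    last_dose_h <- 24 * (spec$treatment_days - 1)
    term_h <- last_dose_h + samp
    animals <- data.frame(animal_id = ids, strain = spec$strain,
                          age_at_start_months = ages_m,
                          study_id = spec$study_id, arm = arm)

    doses <- do.call(rbind, lapply(which(arm == "treated"), function(i) {
      data.frame(animal_id = ids[i],
                 time_h = 24 * (seq_len(spec$treatment_days) - 1),
                 amount = dose_lvl[i], route = spec$route,
                 vehicle = spec$vehicle)
    }))

    has_bsv <- !is.null(noise$pk_bsv) && any(noise$pk_bsv > 0)
    amyloid_eps <- intersect(spec$endpoints, c("sol_ab40", "insol_ab40"))
    conc_eps <- intersect(spec$endpoints, c("plasma_conc", "brain_conc_total"))

    # drug-free trajectory shared by all vehicle animals
    veh_idx <- which(arm == "vehicle")
    veh_sol <- NULL
    if (length(veh_idx) && length(amyloid_eps)) {
      tt <- age_to_hours(ages_m[veh_idx]) + term_h[veh_idx]
      veh_sol <- .pkpd_solve(tt, data.frame(time_h = numeric(),
                                            amt_eff = numeric(), ka = numeric()),
                             pk, pd)
    }

    obs <- list()
    for (i in seq_len(n)) {
      t_term_model <- age_to_hours(ages_m[i]) + term_h[i]
      pk_i <- if (has_bsv && arm[i] == "treated") .draw_pk(pk, noise$pk_bsv) else pk
      d_i <- if (arm[i] == "treated") {
        data.frame(time_h = 24 * (seq_len(spec$treatment_days) - 1) +
                     age_to_hours(ages_m[i]),
                   amount = dose_lvl[i], route = spec$route,
                   vehicle = spec$vehicle)
      } else NULL

      if (length(amyloid_eps)) {
        if (arm[i] == "vehicle") {
          k <- which(veh_sol[, "time"] == age_to_hours(ages_m[i]) + term_h[i])[1]
          mu <- c(sol_ab40 = unname(veh_sol[k, "a_sol"]),
                  insol_ab40 = unname(veh_sol[k, "a_insol"]))
        } else {
          dt <- .dose_table(d_i, pk_i, spec$study_id)
          sol <- .pkpd_solve(t_term_model, dt, pk_i, pd)
          k <- nrow(sol)
          mu <- c(sol_ab40 = unname(sol[k, "a_sol"]),
                  insol_ab40 = unname(sol[k, "a_insol"]))
        }
        for (ep in amyloid_eps) {
          obs[[length(obs) + 1]] <- data.frame(
            animal_id = ids[i], time_h = term_h[i], endpoint = ep,
            value = .draw_noise(mu[[ep]], noise$residual[[ep]]),
            blq_flag = FALSE, lloq = NA_real_)
        }
      }
      if (length(conc_eps) && arm[i] == "treated") {
        cp <- plasma_concentration(term_h[i], d_i_study <- data.frame(
          time_h = 24 * (seq_len(spec$treatment_days) - 1),
          amount = dose_lvl[i], route = spec$route, vehicle = spec$vehicle),
          pk_i, spec$study_id)
        mu <- c(plasma_conc = cp,
                brain_conc_total = brain_concentration(cp, pk_i))
        for (ep in conc_eps) {
          obs[[length(obs) + 1]] <- data.frame(
            animal_id = ids[i], time_h = term_h[i], endpoint = ep,
            value = .draw_noise(mu[[ep]], noise$residual[[ep]]),
            blq_flag = FALSE, lloq = NA_real_)
        }
      }
    }
    as_dataset(animals, doses, do.call(rbind, obs))
  })
}

#' Generate a multi-study benchmark dataset for parameter recovery
#'
#' Bundles a scaled-down version of the in-house study programme suitable
#' for desk-scale recovery experiments: six efficacy studies spanning young
#' (about 5.5-6 months) and old (about 14-20 months) animals with daily
#' oral dosing (a 30-day multiple-dose study, two short dose-ranging
#' studies, a single-dose serial-sacrifice study in the young, and three
#' old-animal studies), plus a drug-free cross-sectional age series whose
#' means come from the same integrated model.  Ages at start are fixed at
#' the nominal design values so that animals within an arm share a dosing
#' history.  Between-subject PK variability is off by default: the
#' benchmark targets the fixed-effect (residual-error-only) recovery
#' setting.
#'
#' @param pk,pd Generating [pk_params()] and [pd_params()] truth.
#' @param noise A [noise_spec()]; the default keeps the published residual
#'   CVs (51% soluble, 83% insoluble) and disables between-subject PK
#'   variability.
#' @param seed Seed for all random draws.
#' @param n_cross Number of drug-free cross-sectional animals.
#' @param studies Which of the bundled design ids to include.
#' @return An [as_dataset()] object.
#' @export
generate_benchmark_dataset <- function(pk = pk_params(), pd = pd_params(),
                                       noise = noise_spec(pk_bsv = NULL),
                                       seed = 1, n_cross = 150,
                                       studies = c("8", "13", "14", "16",
                                                   "17", "18")) {
  designs <- list(
    `8`  = study_design(8, "Tg2576", 24, 30, 15, 30, c(0.5, 6), "oral", 1, 3),
    `13` = study_design(13, "Tg2576", 25, 24, 6, 4, c(1, 3, 7.5), "oral", 1, 3),
    `14` = study_design(14, "Tg2576", 25, 30, 30, 1, 70, "oral", 1,
                        c(3, 6, 24, 48, 120)),
    `16` = study_design(16, "Tg2576", 60, 27, 27, 4, 6, "oral", 1, 3),
    `17` = study_design(17, "Tg2576", 68, 11, 10, 4, 6, "oral", 1, 3),
    `18` = study_design(18, "Tg2576", 85, 40, 40, 1, 70, "oral", 1,
                        c(6, 24, 48, 96))
  )
  studies <- as.character(studies)
  stopifnot(all(studies %in% names(designs)))
  parts <- lapply(seq_along(studies), function(i) {
    generate_study(designs[[studies[i]]], pk, pd, noise, seed = seed + i)
  })
  if (n_cross > 0) {
    parts[[length(parts) + 1]] <- generate_cross_sectional(
      n_cross, c(3.5, 26), noise = noise, seed = seed + 1000L,
      study_id = "xsec", pd = pd, pk = pk)
  }
  bind_datasets(parts)
}

#' Merge several datasets
#'
#' Concatenates the animals, doses and observations of multiple datasets
#' (animal ids must not clash), e.g. to pool several generated studies with
#' a cross-sectional drug-free series before fitting.
#'
#' @param ... `abeta_dataset` objects (or a single list of them).
#' @return A combined [as_dataset()] object.
#' @export
bind_datasets <- function(...) {
  dss <- list(...)
  if (length(dss) == 1 && !inherits(dss[[1]], "abeta_dataset")) dss <- dss[[1]]
  stopifnot(all(vapply(dss, inherits, TRUE, "abeta_dataset")))
  as_dataset(do.call(rbind, lapply(dss, `[[`, "animals")),
             do.call(rbind, lapply(dss, `[[`, "doses")),
             do.call(rbind, lapply(dss, `[[`, "observations")))
}
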