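test_that("the transcribed in-house study designs are complete and well-formed", {
  d <- table1_designs()
  expect_length(d, 23)
  expect_equal(d[["9"]]$treatment_days, 94)
  expect_equal(d[["8"]]$daily_doses, c(0.5, 6))
  expect_equal(d[["18"]]$age_start_weeks, c(81, 89))
  expect_equal(d[["14"]]$sample_times_post_dose_h, c(3, 6, 24, 48, 120))
  for (x in d) {
    expect_true(all(x$daily_doses > 0))
    expect_true(x$route %in% c("oral", "sc", "iv"))
    expect_true(all(x$sample_times_post_dose_h >= 0))
    expect_gte(x$n_treated, 1)
  }
})

test_that("cross-sectional generation is exact without noise and seed-reproducible", {
  apt <- ap_params(variant = "insol_ab40")
  quiet <- noise_spec(residual = NULL)
  ds <- generate_cross_sectional(40, c(3.5, 26), apt, quiet, seed = 6)
  ages <- ds$animals$age_at_start_months[
    match(ds$observations$animal_id, ds$animals$animal_id)]
  expect_equal(ds$observations$value, ap_level(ages, apt))

  ds1 <- generate_cross_sectional(40, c(3.5, 26), apt, noise_spec(), seed = 6)
  ds2 <- generate_cross_sectional(40, c(3.5, 26), apt, noise_spec(), seed = 6)
  expect_identical(ds1, ds2)
  ds3 <- generate_cross_sectional(40, c(3.5, 26), apt, noise_spec(), seed = 7)
  expect_false(identical(ds1$observations$value, ds3$observations$value))
  expect_error(generate_cross_sectional(10, c(26, 3.5)), "range")
})

test_that("generated noise reproduces the target coefficient of variation", {
  apt <- ap_params(variant = "sol_ab40")
  ds <- generate_cross_sectional(5000, ap = apt, noise = noise_spec(),
                                 ages = 15, seed = 10)
  v <- ds$observations$value
  expect_gte(sd(v) / mean(v), 0.45)
  expect_lte(sd(v) / mean(v), 0.57)
  expect_true(all(v > 0))
})

test_that("a serial-sacrifice study yields the designed cohort structure", {
  spec <- study_design(14, "Tg2576", 25, 30, 30, 1, 70, "oral", 1,
                       c(3, 6, 24, 48, 120))
  ds <- generate_study(spec, noise = noise_spec(pk_bsv = NULL), seed = 2)
  expect_equal(nrow(ds$animals), 60)
  expect_gte(length(unique(ds$observations$time_h)), 5)
  expect_equal(sum(ds$animals$arm == "treated"), 30)
  # single dose per treated animal
  expect_equal(nrow(ds$doses), 30)
})

test_that("without noise the treated arm equals the simulator output exactly", {
  spec <- study_design(13, "Tg2576", 25, 3, 2, 4, 6, "oral", 1, 3)
  quiet <- noise_spec(residual = NULL, pk_bsv = NULL)
  ds <- generate_study(spec, noise = quiet, seed = 3)
  tr <- ds$animals$animal_id[ds$animals$arm == "treated"][1]
  age <- ds$animals$age_at_start_months[ds$animals$animal_id == tr]
  dosing <- ds$doses[ds$doses$animal_id == tr, ]
  s <- simulate_pkpd(age, dosing, pd = pd_params(),
                     times_h = age_to_hours(age) + 24 * 3 + 3,
                     study_id = "13")
  ov <- ds$observations[ds$observations$animal_id == tr, ]
  expect_equal(ov$value[ov$endpoint == "sol_ab40"], s$a_sol[length(s$a_sol)],
               tolerance = 1e-6)
  expect_equal(ov$value[ov$endpoint == "insol_ab40"],
               s$a_insol[length(s$a_insol)], tolerance = 1e-6)
})

test_that("vehicle-arm means track the drug-free progression curve", {
  spec <- study_design(16, "Tg2576", 60, 1, 400, 4, 6, "oral", 1, 3)
  ds <- generate_study(spec, noise = noise_spec(pk_bsv = NULL), seed = 11)
  veh <- ds$animals$animal_id[ds$animals$arm == "vehicle"]
  ov <- ds$observations
  sol <- ov[ov$endpoint == "sol_ab40" & ov$animal_id %in% veh, ]
  age_term <- ds$animals$age_at_start_months[
    match(sol$animal_id, ds$animals$animal_id)] + hours_to_age(sol$time_h)
  # the integrated model's drug-free soluble level is the progression curve
  expect_equal(mean(sol$value), mean(ap_level(age_term, pd_params()$ap)),
               tolerance = 0.1)
})

test_that("generated drug-free age trends feed back into progression recovery", {
  # module contract: generator -> fit_ap recovers the generating parameters
  apt <- ap_params(variant = "sol_ab40")
  ds <- generate_cross_sectional(400, c(3.5, 26), apt, noise_spec(), seed = 14)
  f <- fit_ap(ds, "sol_ab40", seed = 1)
  expect_true(f$converged)
  expect_equal(f$estimates[["alpha"]], apt$alpha, tolerance = 0.15)
  expect_equal(f$estimates[["ec_i"]], apt$ec_i, tolerance = 0.15)
  expect_equal(f$estimates[["sd"]], 0.51, tolerance = 0.15)
})

test_that("between-subject PK variability perturbs exposures but not the vehicle arm", {
  spec <- study_design(13, "Tg2576", 25, 6, 3, 2, 6, "oral", 1, 3,
                       endpoints = c("sol_ab40"))
  base <- generate_study(spec, noise = noise_spec(residual = NULL,
                                                  pk_bsv = NULL), seed = 9)
  bsv <- generate_study(spec, noise = noise_spec(residual = NULL), seed = 9)
  tr_ids <- base$animals$animal_id[base$animals$arm == "treated"]
  pick <- function(ds, ids) ds$observations$value[
    ds$observations$animal_id %in% ids]
  expect_false(isTRUE(all.equal(pick(base, tr_ids), pick(bsv, tr_ids))))
  veh_ids <- setdiff(base$animals$animal_id, tr_ids)
  expect_equal(pick(base, veh_ids), pick(bsv, veh_ids))
})
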