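pd <- pd_params()     # final (model C) estimates
pk <- pk_params()

test_that("the Abeta-dependent IC50 reproduces the young/old anchors", {
  expect_equal(ic50_of_level(57.1, 514), 0.111, tolerance = 0.01)
  a25 <- ap_level(25, pd$ap)
  expect_equal(ic50_of_level(a25, 514), 12, tolerance = 0.05)
  expect_equal(ic50_of_level(0, 514), 0)
})

test_that("inhibition term has Hill behaviour with the fitted maximum", {
  expect_equal(inhibition(0, 57.1, pd), 0)
  expect_equal(inhibition(1e9, 57.1, pd), 0.86, tolerance = 1e-6)
  ic50 <- ic50_of_level(57.1, pd$sl)
  expect_equal(inhibition(ic50, 57.1, pd), 0.86 / 2, tolerance = 1e-12)
  pdB <- pd_params(effect_model = "B", imax = 0.7, ic50_fixed = 0.3)
  expect_equal(inhibition(0.3, 100, pdB), 0.35)
  # model A returns an absolute rate with the same Hill midpoint
  pdA <- pd_params(effect_model = "A", imax = 60, ic50_fixed = 0.3)
  expect_equal(inhibition(0.3, 100, pdA), 30)
  expect_error(pd_params(effect_model = "C", sl = NULL), "sl")
})

test_that("the soluble-to-insoluble scaling function is a bounded logistic in time", {
  expect_equal(scale_function(1e9, pd), 6.5, tolerance = 1e-6)
  expect_equal(scale_function(7610, pd), 3.25)
  expect_equal(scale_function(0, pd), 0)
  tt <- seq(0, 25000, by = 100)
  s <- scale_function(tt, pd)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s < 6.5))
})

test_that("asymptotic scaling ties the soluble and insoluble plateaus together", {
  # alpha2 x soluble plateau vs the independently fitted insoluble plateau
  expect_equal(6.5 * 6620, 39900, tolerance = 0.15)
})

test_that("right-hand side encodes production/loss balance and drug action", {
  # drug-free quasi-steady state: production matches loss up to the slow
  # progression drift
  age <- 12
  a_eq <- ap_level(age, pd$ap)
  d <- pkpd_rhs(age_to_hours(age), c(a_eq, 500), 0, pd)
  expect_lt(abs(d[["a_sol"]]) / (pd$kout_sol * a_eq), 1e-3)
  # full inhibition at steady state: pure first-order loss
  pdB <- pd_params(effect_model = "B", imax = 1, ic50_fixed = 1e-12)
  d2 <- pkpd_rhs(age_to_hours(age), c(a_eq, 500), 1e6, pdB)
  expect_equal(d2[["a_sol"]], -pdB$kout_sol * a_eq, tolerance = 1e-6)
  # insoluble pool decays with ~30-day half-life when its production is off
  pd0 <- pd_params(baseline_insol = 1e-12)
  dI <- pkpd_rhs(1, c(0, 100), 0, pd0)
  expect_equal(dI[["a_insol"]], -0.001 * 100, tolerance = 1e-6)
  expect_equal(log(2) / pd0$kout_insol / 24, 28.9, tolerance = 0.01)
})

test_that("drug-free simulation reproduces the progression curve", {
  s <- simulate_pkpd(24, NULL, pk, pd, duration_h = 24 * 30)
  sel <- s$age_months >= 1
  expect_lt(max(abs(s$a_sol[sel] / s$ap_ref[sel] - 1)), 0.01)
  # insoluble tracks its own moving equilibrium with the slow turnover lag
  eq <- pd$baseline_insol + scale_function(s$times_h, pd) * s$a_sol
  i <- length(eq)
  expect_lt(abs(s$a_insol[i] / eq[i] - 1), 0.35)
  expect_true(all(s$a_sol >= 0 & s$a_insol >= 0 & s$c_brain == 0))
})

test_that("compiled integration agrees with the pure-R Runge-Kutta oracle", {
  dosing <- data.frame(time_h = seq(0, 24 * 6, by = 24), amount = 6,
                       route = "oral", vehicle = 1)
  for (age in c(5, 15)) {
    s1 <- simulate_pkpd(age, dosing, pk, pd, duration_h = 24 * 8)
    s2 <- simulate_pkpd(age, dosing, pk, pd, duration_h = 24 * 8,
                        compiled = FALSE, method = "ode45",
                        rtol = 1e-9, atol = 1e-11)
    expect_lt(max(abs(s1$a_sol / s2$a_sol - 1)), 0.005)
    expect_lt(max(abs(s1$a_insol / s2$a_insol - 1)), 0.005)
  }
})

test_that("states stay positive under aggressive dosing", {
  dosing <- data.frame(time_h = seq(0, 24 * 13, by = 12), amount = 70,
                       route = "oral", vehicle = 2)
  s <- simulate_pkpd(5, dosing, pk, pd, duration_h = 24 * 20)
  expect_true(all(s$a_sol >= 0))
  expect_true(all(s$a_insol >= 0))
  pdA <- pd_params(effect_model = "A", imax = 500, ic50_fixed = 0.1)
  sA <- simulate_pkpd(5, dosing, pk, pdA, duration_h = 24 * 20)
  expect_true(all(sA$a_sol >= -1e-9))
})

test_that("relative drug effect is age-invariant under model B, age-fading under C", {
  dosing <- data.frame(time_h = seq(0, 24 * 27, by = 24), amount = 6,
                       route = "oral", vehicle = 1)
  red <- function(pdm, age) {
    s <- simulate_pkpd(age, dosing, pk, pdm, duration_h = 24 * 28)
    average_soluble_reduction(s, age_to_hours(age) + c(24 * 14, 24 * 28))
  }
  pdB <- pd_params(effect_model = "B", imax = 0.86, ic50_fixed = 0.111)
  expect_equal(red(pdB, 5), red(pdB, 15), tolerance = 0.01)
  expect_gt(red(pd, 5), 2 * red(pd, 15))
  # model A: absolute reduction is age-invariant
  pdA <- pd_params(effect_model = "A", imax = 30, ic50_fixed = 0.111)
  abs_red <- function(age) {
    s <- simulate_pkpd(age, dosing, pk, pdA, duration_h = 24 * 28)
    w <- s$times_h >= age_to_hours(age) + 24 * 14
    mean((s$ap_ref - s$a_sol)[w])
  }
  expect_equal(abs_red(5), abs_red(15), tolerance = 0.15)
})

test_that("soluble pool responds to a drug step on its 38-minute timescale", {
  pdB <- pd_params(effect_model = "B", imax = 0.86, ic50_fixed = 0.001)
  dos <- data.frame(time_h = 0, amount = 70, route = "iv", vehicle = 1)
  t0 <- age_to_hours(5)
  s <- simulate_pkpd(5, dos, pk, pdB, times_h = seq(t0 - 24, t0 + 12, by = 0.05))
  a0 <- s$a_sol[s$times_h == t0]
  floorv <- (1 - pdB$imax) * ap_level(5, pdB$ap)
  mid <- floorv + (a0 - floorv) / 2
  t_half <- min(s$times_h[s$times_h > t0 & s$a_sol < mid]) - t0
  expect_equal(t_half * 60, log(2) / 1.1 * 60, tolerance = 0.15)
})

test_that("average soluble reduction summarises the treatment window correctly", {
  s0 <- simulate_pkpd(5, NULL, pk, pd, duration_h = 24 * 10)
  expect_lt(abs(average_soluble_reduction(
    s0, age_to_hours(5) + c(0, 24 * 10))), 0.01)
  # sustained near-complete saturation approaches the 86% ceiling
  pdB <- pd_params(effect_model = "B", imax = 0.86, ic50_fixed = 1e-6)
  dosing <- data.frame(time_h = seq(0, 24 * 9, by = 24), amount = 30,
                       route = "oral", vehicle = 2)
  s1 <- simulate_pkpd(5, dosing, pk, pdB, duration_h = 24 * 10)
  expect_equal(average_soluble_reduction(
    s1, age_to_hours(5) + c(24, 24 * 10)), 86, tolerance = 0.02)
  # a single dose: the window average is below the trough (peak) reduction
  one <- data.frame(time_h = 0, amount = 70, route = "oral", vehicle = 1)
  s2 <- simulate_pkpd(5, one, pk, pd, duration_h = 24 * 5)
  avg <- average_soluble_reduction(s2, age_to_hours(5) + c(0, 24 * 5))
  trough <- max(100 * (1 - s2$a_sol / s2$ap_ref))
  expect_lt(avg, trough)
  expect_error(average_soluble_reduction(s2, c(0, 1e9)), "span")
  expect_error(average_soluble_reduction(s2, c(5, 5)), "increasing")
})
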