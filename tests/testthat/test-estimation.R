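apt <- ap_params(variant = "sol_ab40")

test_that("the pooled objective matches a hand-written Gaussian likelihood", {
  obs <- c(48, 60, 1500, 5200, 6400)
  pred <- c(50, 55, 1400, 5500, 6300)
  expect_equal(negloglik(obs, pred, error_model("additive", 120)),
               brute_force_nll_additive(obs, pred, 120), tolerance = 1e-12)
  # proportional kind: mean-parameterised log-normal, matches dlnorm
  em <- error_model("proportional", 0.51)
  sdlog <- sqrt(log1p(0.51^2))
  byhand <- -2 * sum(dlnorm(obs, log(pred) - sdlog^2 / 2, sdlog, log = TRUE))
  expect_equal(negloglik(obs, pred, em), byhand, tolerance = 1e-12)
  # the mean parameterisation is unbiased: E[draw] equals the prediction
  set.seed(9)
  draws <- apgsi:::.draw_noise(rep(1000, 2e5), em)
  expect_equal(mean(draws), 1000, tolerance = 0.01)
})

test_that("perturbing any parameter away from a noise-free optimum raises the objective", {
  ages <- seq(3.5, 26, length.out = 60)
  df <- data.frame(age_months = ages, value = ap_level(ages, apt))
  base <- negloglik(df$value, ap_level(ages, apt), error_model("additive", 5))
  for (perturb in list(c(alpha = 1.1), c(ec_i = 0.9), c(p = 1.2),
                       c(baseline = 1.3))) {
    pv <- list(alpha = apt$alpha, ec_i = apt$ec_i, p = apt$p,
               baseline = apt$baseline)
    pv[[names(perturb)]] <- pv[[names(perturb)]] * perturb
    pred <- ap_level(ages, ap_params(pv$alpha, pv$ec_i, pv$p, pv$baseline))
    expect_gt(negloglik(df$value, pred, error_model("additive", 5)), base)
  }
})

test_that("noise-free progression data are recovered essentially exactly", {
  ages <- rep(seq(3.5, 26, length.out = 25), each = 4)
  df <- data.frame(age_months = ages, value = ap_level(ages, apt))
  f <- fit_ap(df, "sol_ab40", error_kind = "additive",
              init = list(alpha = 3000, ec_i = 14, p = 4, baseline = 100,
                          sd = 10),
              fixed = c(sd = 1), n_start = 6, seed = 2)
  expect_true(f$converged)
  for (nm in c("alpha", "ec_i", "p", "baseline")) {
    expect_equal(f$estimates[[nm]], apt[[nm]], tolerance = 1e-3)
  }
})

test_that("young-only data leave the plateau non-identifiable and flagged", {
  ds <- generate_cross_sectional(200, c(3.5, 9.5), apt, noise_spec(), seed = 3)
  f <- fit_ap(ds, "sol_ab40", seed = 1)
  expect_true(f$flags[["alpha"]])
})

test_that("standard errors match the closed-form linear-regression oracle", {
  # with only the plateau free, the prediction is linear in it:
  # pred = alpha * w(age) + baseline * (1 - w(age)), so the additive-error
  # MLE is weighted least squares with SE = sd / sqrt(sum(w^2))
  ages <- rep(c(4, 8, 12, 16, 20, 24, 28), each = 5)
  set.seed(42)
  vals <- ap_level(ages, apt) + rnorm(length(ages), 0, 100)
  f <- fit_ap(data.frame(age_months = ages, value = vals), "sol_ab40",
              error_kind = "additive",
              init = list(alpha = 6640, ec_i = 20, p = 6.4, baseline = 48,
                          sd = 100),
              fixed = c(ec_i = 20, p = 6.4, baseline = 48, sd = 100),
              n_start = 3)
  w <- (ages / 20)^6.4 / (1 + (ages / 20)^6.4)
  alpha_hat <- sum(w * (vals - 48 * (1 - w))) / sum(w^2)
  expect_equal(f$estimates[["alpha"]], alpha_hat, tolerance = 1e-4)
  expect_equal(f$se[["alpha"]], 100 / sqrt(sum(w^2)), tolerance = 1e-3)
  # fixed parameters carry no SE
  expect_false("p" %in% names(f$se))
  expect_identical(standard_errors(f), f$se)
})

test_that("standard errors shrink roughly as one over root n", {
  ds <- generate_cross_sectional(1000, c(3.5, 26), apt, noise_spec(), seed = 8)
  keep <- ds$animals$animal_id[1:500]
  half <- as_dataset(ds$animals[1:500, ], NULL,
                     ds$observations[ds$observations$animal_id %in% keep, ])
  fA <- fit_ap(half, seed = 1)
  fB <- fit_ap(ds, seed = 1)
  expect_equal(fA$se[["alpha"]] / fB$se[["alpha"]], sqrt(2), tolerance = 0.2)
})

test_that("the objective trace improves monotonically in its running minimum", {
  ds <- generate_cross_sectional(150, c(3.5, 26), apt, noise_spec(), seed = 5)
  f <- fit_ap(ds, seed = 1)
  cm <- cummin(f$ofv_trace)
  expect_true(all(diff(cm) <= 0))
  expect_equal(min(f$ofv_trace), f$ofv, tolerance = 1e-9)
  expect_lt(f$ofv, f$ofv_trace[1])
})

test_that("noise-free integrated model C data recover Imax and SL within 1%", {
  ds <- generate_benchmark_dataset(noise = noise_spec(residual = NULL,
                                                      pk_bsv = NULL),
                                   seed = 5, n_cross = 60,
                                   studies = c("13", "14", "16"))
  init <- pd_params(imax = 0.7, sl = 300,
                    ap = ap_params(5000, 15, 6, 45, "sol_ab40"),
                    kout_insol = 0.002, baseline_insol = 20, alpha2 = 5,
                    ec_i2 = 6000, p2 = 7)
  f <- fit_pkpd(ds, effect_model = "C", init = init,
                fixed = c("kout_sol", "sd_sol", "sd_insol"),
                error_kind = "additive_log", n_start = 1, seed = 1, se = FALSE,
                control = list(eval.max = 3000, iter.max = 500))
  expect_equal(f$estimates[["imax"]], 0.86, tolerance = 0.01)
  expect_equal(f$estimates[["sl"]], 514, tolerance = 0.01)
})

test_that("model B fitted to young+old model-C data is beaten by model C", {
  fixed_common <- c("alpha", "ec_i", "p", "baseline", "kout_sol",
                    "kout_insol", "baseline_insol", "alpha2", "ec_i2", "p2")
  ds <- generate_benchmark_dataset(noise = noise_spec(pk_bsv = NULL),
                                   seed = 21, n_cross = 0,
                                   studies = c("13", "16", "17"))
  fB <- fit_pkpd(ds, effect_model = "B",
                 init = pd_params(effect_model = "B", imax = 0.8,
                                  ic50_fixed = 0.3),
                 fixed = fixed_common, endpoints = "sol_ab40",
                 n_start = 1, se = FALSE)
  fC <- fit_pkpd(ds, effect_model = "C",
                 init = pd_params(imax = 0.8, sl = 300),
                 fixed = fixed_common, endpoints = "sol_ab40",
                 n_start = 1, se = FALSE)
  expect_gt(fB$ofv, fC$ofv)
  cmp <- compare_models(B = fB, C = fC)
  expect_equal(cmp$model[1], "C")
})

test_that("parametric simulation from a fit is reproducible and centred on it", {
  ds <- generate_cross_sectional(120, c(3.5, 26), apt, noise_spec(), seed = 17)
  f <- fit_ap(ds, seed = 1)
  s1 <- simulate(f, nsim = 3, seed = 4)
  s2 <- simulate(f, nsim = 3, seed = 4)
  expect_identical(s1, s2)
  big <- simulate(f, nsim = 200, seed = 4)
  avg <- rowMeans(sapply(big, `[[`, "value"))
  expect_equal(mean(avg / predict(f)), 1, tolerance = 0.02)
})

test_that("model ranking handles ties and refuses mismatched datasets", {
  ds <- generate_cross_sectional(100, c(3.5, 26), apt, noise_spec(), seed = 12)
  f1 <- fit_ap(ds, seed = 1)
  cmp <- compare_models(a = f1, b = f1)
  expect_equal(cmp$rank, c(1L, 1L))
  # an independent multi-start run lands on the same optimum
  f2 <- fit_ap(ds, seed = 7)
  expect_equal(f2$ofv, f1$ofv, tolerance = 1e-6)
  other <- generate_cross_sectional(100, c(3.5, 26), apt, noise_spec(),
                                    seed = 13)
  f3 <- fit_ap(other, seed = 1)
  expect_error(compare_models(f1, f3), "same dataset")
})
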