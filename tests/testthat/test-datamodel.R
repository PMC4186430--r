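test_that("age/time unit conversions are exact inverses on the fixed convention", {
  expect_equal(age_to_hours(0), 0)
  expect_equal(age_to_hours(1), 730.5)
  # the published scaling-function inflection of 7610 h sits near 10.4 months
  expect_equal(age_to_hours(10.42), 7611.81)
  expect_equal(hours_to_age(age_to_hours(17.3)), 17.3)
  ages <- c(0, 0.01, 3.5, 18.1, 26)
  expect_identical(hours_to_age(age_to_hours(ages)), ages)
  expect_error(age_to_hours(-1), "non-negative")
  expect_error(hours_to_age(-5), "non-negative")
})

test_that("a minimal event-record file round-trips through read/write", {
  path <- tempfile(fileext = ".csv")
  write_fixture_csv(path, c(
    "m1,0,.,6,1,.,5.5,oral,1,8,treated,.,Tg2576",
    "m1,3,42.5,.,0,3,5.5,.,.,8,treated,.,Tg2576"
  ))
  ds <- read_dataset(path)
  expect_s3_class(ds, "abeta_dataset")
  expect_equal(nrow(ds$animals), 1)
  expect_equal(nrow(ds$doses), 1)
  expect_equal(nrow(ds$observations), 1)
  expect_equal(ds$doses$amount, 6)
  expect_equal(ds$observations$endpoint, "sol_ab40")
  expect_equal(ds$observations$value, 42.5)

  out <- tempfile(fileext = ".csv")
  write_dataset(ds, out)
  ds2 <- read_dataset(out)
  expect_equal(ds2, ds)
})

test_that("round trip is lossless on a generated multi-endpoint dataset", {
  ds <- generate_study(study_design(13, "Tg2576", 25, 6, 3, 4, c(1, 3), "oral",
                                    1, 3),
                       noise = noise_spec(pk_bsv = NULL), seed = 4)
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  ds2 <- read_dataset(path)
  expect_equal(ds2$animals, ds$animals)
  expect_equal(ds2$doses, ds$doses)
  expect_equal(ds2$observations, ds$observations, tolerance = 1e-12)
})

test_that("values below the LLOQ column are flagged on read", {
  path <- tempfile(fileext = ".csv")
  write_fixture_csv(path, c(
    "m1,0,0.005,.,0,1,6,.,.,5,treated,0.01,C57BL/6",
    "m1,3,0.500,.,0,1,6,.,.,5,treated,0.01,C57BL/6"
  ))
  ds <- read_dataset(path)
  expect_identical(ds$observations$blq_flag, c(TRUE, FALSE))
})

test_that("schema and validation errors are raised for malformed files", {
  p1 <- tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,DV", "m1,0,1"), p1)
  expect_error(read_dataset(p1), "missing column")

  p2 <- tempfile(fileext = ".csv")
  write_fixture_csv(p2, "m1,0,.,-3,1,.,5.5,oral,1,8,treated,.,Tg2576")
  expect_error(read_dataset(p2), "positive AMT")

  p3 <- tempfile(fileext = ".csv")
  write_fixture_csv(p3, "m1,0,4,.,0,9,5.5,.,.,8,treated,.,Tg2576")
  expect_error(read_dataset(p3), "DVID")
})

test_that("dataset constructor enforces referential and domain invariants", {
  an <- data.frame(animal_id = "a1", strain = "Tg2576",
                   age_at_start_months = 6, study_id = "s", arm = "treated")
  expect_error(as_dataset(an, doses = data.frame(
    animal_id = "ghost", time_h = 0, amount = 1, route = "oral", vehicle = 1)),
    "unknown animal_id")
  expect_error(as_dataset(an, observations = data.frame(
    animal_id = "a1", time_h = 0, endpoint = "sol_ab40", value = -2)),
    "flagged BLQ")
  expect_error(as_dataset(an[, setdiff(names(an), "age_at_start_months")]),
    "missing column")
})

test_that("BLQ exclusion removes exactly the flagged rows and reports fractions", {
  n <- 80
  an <- data.frame(animal_id = sprintf("a%02d", 1:n), strain = "Tg2576",
                   age_at_start_months = 6, study_id = "s", arm = "vehicle")
  blq <- rep(FALSE, n); blq[1:2] <- TRUE   # 2.5% of plasma rows below LLOQ
  obs <- data.frame(animal_id = an$animal_id, time_h = 1,
                    endpoint = "plasma_conc",
                    value = ifelse(blq, 0.001, 1), blq_flag = blq, lloq = 0.01)
  obs2 <- data.frame(animal_id = an$animal_id[1:10], time_h = 2,
                     endpoint = "sol_ab40", value = 50, blq_flag = FALSE,
                     lloq = NA_real_)
  ds <- as_dataset(an, NULL, rbind(obs, obs2))

  res <- exclude_blq(ds, "plasma_conc")
  rep_pl <- res$report[res$report$endpoint == "plasma_conc", ]
  expect_equal(rep_pl$fraction_excluded, 0.025)
  expect_equal(nrow(res$dataset$observations) + rep_pl$n_excluded,
               nrow(ds$observations))
  # non-flagged observations are untouched
  expect_true(all(!res$dataset$observations$blq_flag[
    res$dataset$observations$endpoint == "plasma_conc"]))
  expect_equal(sum(res$dataset$observations$endpoint == "sol_ab40"), 10)

  # no-BLQ and all-BLQ degenerate cases
  res2 <- exclude_blq(res$dataset, "plasma_conc")
  expect_equal(res2$dataset, res$dataset)
  all_blq <- as_dataset(an[1:2, ], NULL, obs[1:2, ])
  res3 <- exclude_blq(all_blq, "plasma_conc")
  expect_equal(nrow(res3$dataset$observations), 0)
  expect_equal(res3$report$fraction_excluded[
    res3$report$endpoint == "plasma_conc"], 1)
})

test_that("parameter configuration files read back as named lists", {
  py <- tempfile(fileext = ".yaml")
  writeLines(c("CL: 0.12", "V2: 0.28", "Imax: 0.86"), py)
  expect_equal(read_params(py)$V2, 0.28)
  pj <- tempfile(fileext = ".json")
  writeLines('{"SL": 514, "EC_i": 18.1}', pj)
  expect_equal(read_params(pj)$SL, 514)
})
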