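test_that("validation accepts well-formed records and reports violations by field and rule", {
  v <- validate_case(healthy_case())
  expect_true(v$valid)
  expect_identical(nrow(v$errors), 0L)

  v <- validate_case(healthy_case(current_weight_g = 25000))
  expect_false(v$valid)
  expect_true(any(v$errors$field == "current_weight_g" & v$errors$rule == "range"))

  v <- validate_case(healthy_case(
    assessment_datetime = as.POSIXct("2017-02-28 08:00", tz = "UTC")))
  expect_false(v$valid)
  expect_true(any(v$errors$field == "assessment_datetime" & v$errors$rule == "ordering"))

  # multiple violations collected in one pass
  v <- validate_case(healthy_case(current_weight_g = 25000, temperature = 60))
  expect_identical(nrow(v$errors), 2L)
})

test_that("postnatal age floors to whole days and drives the 28-day eligibility cut", {
  expect_identical(postnatal_age_days(as.POSIXct("2017-03-01 08:00", tz = "UTC"),
                                      as.POSIXct("2017-03-07 10:00", tz = "UTC")), 6L)
  t0 <- as.POSIXct("2017-03-01 08:00", tz = "UTC")
  expect_identical(postnatal_age_days(t0, t0), 0L)
  expect_error(postnatal_age_days(t0, t0 - 86400), "precedes")

  cs <- healthy_case(birth_datetime = "2017-03-01 00:00",
                     assessment_datetime = "2017-03-29 00:00")
  d <- derive_measures(cs)
  expect_identical(d$postnatal_age_days, 28L)
  expect_false(d$eligible)

  # monotone non-decreasing in the assessment time
  ages <- vapply(seq(0, 40, by = 0.5), function(dd) {
    postnatal_age_days(t0, t0 + dd * 86400)
  }, integer(1))
  expect_true(all(diff(ages) >= 0))
})

test_that("gestational age is exact days/7 with a strict preterm cut at 37 weeks", {
  ga <- gestational_age_weeks(as.Date("2016-06-01"), as.Date("2017-03-08"))
  expect_equal(ga, 40.0)
  expect_equal(gestational_age_weeks(as.Date("2017-01-01"),
                                     as.Date("2017-01-01") + 259), 37.0)
  expect_equal(gestational_age_weeks(as.Date("2017-01-01"),
                                     as.Date("2017-01-01") + 252), 36.0)
  expect_error(gestational_age_weeks(as.Date("2017-03-09"), as.Date("2017-03-08")),
               "LMP after birth")

  for (days in c(180L, 252L, 259L, 280L, 300L)) {
    ga <- gestational_age_weeks(as.Date("2016-06-01"), as.Date("2016-06-01") + days)
    expect_equal(ga * 7, days)  # exact before any display rounding
  }

  d <- derive_measures(healthy_case(lmp_date = as.Date("2017-03-01") - 252))
  expect_true(d$preterm)
  d <- derive_measures(healthy_case(lmp_date = as.Date("2017-03-01") - 259))
  expect_false(d$preterm)
  d <- derive_measures(healthy_case(lmp_date = NA))
  expect_true(is.na(d$gestational_age_weeks))
  expect_true(is.na(d$preterm))
})

test_that("weight change is a signed percent of birth weight", {
  expect_equal(weight_change_percent(2500, 2250), -10)
  expect_equal(weight_change_percent(2500, 2500), 0)
  expect_equal(weight_change_percent(2000, 2100), 5)
  expect_error(weight_change_percent(0, 2100), "positive")
})

test_that("temperatures normalize to Celsius at 0.1 resolution", {
  expect_equal(normalize_temperature(100.4, "F"), 38.0)
  expect_equal(normalize_temperature(95.9, "F"), 35.5)
  expect_equal(normalize_temperature(37.0, "C"), 37.0)
  expect_error(normalize_temperature(37.0, "K"))

  # F -> C -> F recovers the input within the 0.1-degC storage resolution
  set.seed(42)
  for (f in round(runif(50, 86, 106), 1)) {
    c_val <- normalize_temperature(f, "F")
    back <- c_val * 9 / 5 + 32
    expect_lt(abs(back - f), 0.1 * 9 / 5 + 1e-9)
  }
})

test_that("case files round-trip through CSV and JSON unchanged", {
  set.seed(11)
  cases <- lapply(1:12, random_valid_case)
  for (ext in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_cases(cases, path)
    back <- read_cases(path)
    expect_length(back, length(cases))
    for (i in seq_along(cases)) expect_equal(back[[i]], cases[[i]])
    unlink(path)
  }
})
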