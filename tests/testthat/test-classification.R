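cfg <- classification_config()

test_that("size classification combines weight, foot length and availability", {
  dm <- function(cs) derive_measures(cs)
  cs <- healthy_case(birth_weight_g = 2400, current_weight_g = 2400)
  s <- classify_size(cs, dm(cs), cfg)
  expect_identical(unname(s[c("low_birth_weight", "small")]), c("positive", "positive"))

  cs <- healthy_case(birth_weight_g = 2600, current_weight_g = 2600, foot_length_mm = 73)
  s <- classify_size(cs, dm(cs), cfg)
  expect_identical(unname(s[["low_birth_weight"]]), "negative")
  expect_identical(unname(s[["small"]]), "positive")

  cs <- healthy_case(birth_weight_g = 2550, current_weight_g = 1450)
  s <- classify_size(cs, dm(cs), cfg)
  expect_identical(unname(s[["very_low_weight_lt1500"]]), "positive")

  # missing inputs: na only when nothing is evaluable
  cs <- healthy_case(birth_weight_g = NA, current_weight_g = 3000, foot_length_mm = NA)
  s <- classify_size(cs, dm(cs), cfg)
  expect_identical(unname(s[["low_birth_weight"]]), "na")
  expect_identical(unname(s[["small"]]), "na")
  expect_identical(unname(s[["very_low_weight_lt1500"]]), "negative")

  cs <- healthy_case(birth_weight_g = 3000, foot_length_mm = NA)
  s <- classify_size(cs, dm(cs), cfg)
  expect_identical(unname(s[["small"]]), "negative")  # never na with a birth weight
})

test_that("weight-loss bands are closed for moderate and strict for severe", {
  expect_identical(classify_weight_loss(-11, TRUE, cfg), "severe")
  expect_identical(classify_weight_loss(-10, TRUE, cfg), "moderate")
  expect_identical(classify_weight_loss(-8, TRUE, cfg), "moderate")
  expect_identical(classify_weight_loss(-12, FALSE, cfg), "moderate")
  expect_identical(classify_weight_loss(-15, FALSE, cfg), "moderate")
  expect_identical(classify_weight_loss(-15.01, FALSE, cfg), "severe")
  expect_identical(classify_weight_loss(3, FALSE, cfg), "none")
  expect_identical(classify_weight_loss(3, TRUE, cfg), "none")

  # unresolved size falls back to the non-small bands by default
  expect_identical(classify_weight_loss(-12, NA, cfg), "moderate")
  expect_identical(classify_weight_loss(-9, NA, cfg), "none")

  # exactly one category over a fine grid, both sizes
  for (small in c(TRUE, FALSE)) {
    for (pct in seq(-25, 10, by = 0.25)) {
      res <- classify_weight_loss(pct, small, cfg)
      expect_true(res %in% c("none", "moderate", "severe"))
    }
  }
})

test_that("vital-sign thresholds are strict inequalities", {
  v <- classify_vitals(38.5, 55, cfg)
  expect_identical(unname(v), c("positive", "negative", "negative"))
  v <- classify_vitals(35.0, 40, cfg)
  expect_identical(unname(v), c("negative", "positive", "negative"))
  v <- classify_vitals(37.0, 60, cfg)
  expect_identical(unname(v), c("negative", "negative", "negative"))
  v <- classify_vitals(NA, NA, cfg)
  expect_identical(unname(v), c("na", "na", "na"))

  # monotone: colder never clears hypothermia, faster never clears fast breathing
  for (t in seq(35.4, 30, by = -0.5)) {
    expect_identical(unname(classify_vitals(t, 40, cfg)[["hypothermia"]]), "positive")
  }
  for (r in 61:90) {
    expect_identical(unname(classify_vitals(37, r, cfg)[["fast_breathing"]]), "positive")
  }
})

test_that("feeding composites fire on any problematic item and resolve negative only when complete", {
  cs <- healthy_case()
  cs$feeding_intolerance["bloody_stools"] <- "yes"
  f <- classify_feeding(cs)
  expect_identical(unname(f[["feeding_intolerance"]]), "positive")

  f <- classify_feeding(healthy_case())
  expect_identical(unname(f[["feeding_intolerance"]]), "negative")
  expect_identical(unname(f[["breastfeeding_problems"]]), "negative")

  cs <- healthy_case()
  cs$breastfeeding["five_plus_wet_diapers"] <- "no"
  f <- classify_feeding(cs)
  expect_identical(unname(f[["breastfeeding_problems"]]), "positive")

  # unassessed item blocks a negative but not a positive
  cs <- healthy_case()
  cs$feeding_intolerance["frequent_vomiting"] <- "na"
  expect_identical(unname(classify_feeding(cs)[["feeding_intolerance"]]), "na")
  cs$feeding_intolerance["bloody_stools"] <- "yes"
  expect_identical(unname(classify_feeding(cs)[["feeding_intolerance"]]), "positive")
})

test_that("classify_case composes the full profile deterministically", {
  p <- classify_case(healthy_case(), cfg)
  expect_true(all(p$conditions == "negative"))
  expect_false(p$any_danger_sign)
  expect_true(p$eligible)
  expect_identical(p$preterm, "negative")

  p <- classify_case(healthy_case(lmp_date = NA), cfg)
  expect_identical(p$preterm, "na")
  expect_true(is.na(p$derived$gestational_age_weeks))

  p <- classify_case(healthy_case(temperature = 38.5), cfg)
  expect_identical(unname(p$conditions[["fever"]]), "positive")
  expect_true(p$any_danger_sign)
  expect_true(sum(p$conditions == "positive") == 1L)

  p1 <- classify_case(healthy_case(temperature = 38.5), cfg)
  expect_identical(p1$conditions, p$conditions)
})

test_that("Fahrenheit input classifies identically to its Celsius conversion", {
  for (f in c(94.0, 95.9, 96.0, 100.4, 100.5, 104.0)) {
    pf <- classify_case(healthy_case(temperature = f, temperature_unit = "F"), cfg)
    pc <- classify_case(healthy_case(temperature = normalize_temperature(f, "F"),
                                     temperature_unit = "C"), cfg)
    expect_identical(pf$conditions, pc$conditions)
  }
})

test_that("classifier agrees with the brute-force threshold oracle on random cases", {
  set.seed(2024)
  for (i in 1:500) {
    cs <- random_valid_case(i)
    p <- classify_case(cs, cfg)
    o <- oracle_classify(cs, cfg)
    expect_identical(unname(p$conditions[names(o)]), unname(c(o)),
                     label = paste("case", i))
    expect_identical(p$any_danger_sign, attr(o, "any_danger_sign"))
    expect_identical(p$preterm, attr(o, "preterm"))
  }
})
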