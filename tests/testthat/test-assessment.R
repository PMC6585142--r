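schema <- cncp_form_schema()

test_that("next_item walks the schema in order, honouring skip logic", {
  expect_identical(next_item(schema, list()), "infant_id")

  # LMP unknown skips the LMP date (and its computed gestational age)
  ans <- list(infant_id = "x", sex = "female",
              birth_datetime = as.POSIXct("2017-03-01 08:00", tz = "UTC"),
              assessment_datetime = as.POSIXct("2017-03-05 08:00", tz = "UTC"),
              lmp_known = "no")
  expect_identical(next_item(schema, ans), "birth_weight_known")

  ans$lmp_known <- "yes"
  expect_identical(next_item(schema, ans), "lmp_date")

  expect_error(next_item(schema, list(bogus_item = 1)), "unknown item")
})

test_that("the small-baby-care section is skipped for non-small infants", {
  fill <- function(case) run_form(schema, mobile_answers_for(case))
  small_case <- healthy_case(birth_weight_g = 2300, current_weight_g = 2250,
                             foot_length_mm = 70)
  a <- fill(small_case)
  expect_true("kmc_counseled" %in% names(a))

  a <- fill(healthy_case())
  expect_false("kmc_counseled" %in% names(a))
  expect_false("skin_to_skin_hours" %in% names(a))
})

test_that("response validation enforces ranges, choices and double entry", {
  wt <- schema$items[[which(schema$ids == "birth_weight_g")]]
  expect_true(validate_response(wt, 2500, previous_entry = 2500)$accepted)
  chk <- validate_response(wt, 2600, previous_entry = 2500)
  expect_false(chk$accepted)
  expect_identical(chk$violations$rule, "double_entry")

  tp <- schema$items[[which(schema$ids == "temperature_c")]]
  chk <- validate_response(tp, 50)
  expect_false(chk$accepted)
  expect_identical(chk$violations$rule, "range")

  # implausible-but-legal values warn without blocking
  chk <- validate_response(tp, 33.0)
  expect_true(chk$accepted)
  expect_identical(chk$warnings$rule, "plausibility")

  sx <- schema$items[[which(schema$ids == "sex")]]
  expect_false(validate_response(sx, "unknown")$accepted)
})

test_that("schema invariants reject forward references and duplicate ids", {
  expect_error(form_schema(list(
    form_item("a", type = "choice", choices = c("yes", "no"),
              skip = quote(b == "yes")),
    form_item("b", type = "choice", choices = c("yes", "no"))
  )), "non-earlier")
  expect_error(form_schema(list(form_item("a"), form_item("a"))), "duplicate")
})

test_that("engine-driven records always audit as fully complete", {
  set.seed(5)
  for (i in 1:10) {
    cs <- random_valid_case(i)
    # the engine requires resolvable entries: give the case full measurements
    cs$birth_weight_g <- 3000; cs$current_weight_g <- 2900
    cs$foot_length_mm <- 80; cs$temperature <- 37; cs$temperature_unit <- "C"
    cs$breath_count_60s <- 44
    cs$signs[] <- sample(c("yes", "no"), length(cs$signs), replace = TRUE)
    cs$feeding_intolerance[] <- "no"; cs$breastfeeding[] <- "yes"
    a <- run_form(schema, mobile_answers_for(cs))
    rec <- assessment_record("mobile", "chw01", cs$infant_id, a,
                             recommendations = "follow-up", schema = schema)
    fl <- completeness_report(rec)
    expect_true(fl$full_assessment)
    expect_true(fl$rr_recorded && fl$temp_recorded && fl$weight_recorded)
    expect_true(fl$weight_loss_calculated && fl$postnatal_age_calculated)
  }
})

test_that("completeness flags reflect missing fields on paper records", {
  ans <- list(sign_poor_movement = "no")
  for (nm in sign_names()) ans[[paste0("sign_", nm)]] <- "no"
  ans$temperature_c <- 37; ans$birth_weight_g <- 3000
  ans$breath_count_60s <- NA
  rec <- assessment_record("paper", "chw02", "i1", ans, recommendations = "advice")
  fl <- completeness_report(rec)
  expect_false(fl$rr_recorded)
  expect_false(fl$full_assessment)
  expect_true(fl$temp_recorded && fl$weight_recorded && fl$any_recommendation)

  # LMP recorded but gestational age never calculated
  ans$breath_count_60s <- 50
  ans$lmp_date <- "2016-06-01"; ans$ga_weeks <- NA
  fl <- completeness_report(assessment_record("paper", "chw02", "i1", ans,
                                              recommendations = "advice"))
  expect_false(fl$ga_calculated_if_lmp)
  expect_true(fl$full_assessment)

  # the flag is vacuous (NA) without an LMP
  ans$lmp_date <- NA
  fl <- completeness_report(assessment_record("paper", "chw02", "i1", ans))
  expect_true(is.na(fl$ga_calculated_if_lmp))
})

test_that("mobile records cannot omit required items", {
  ans <- list()
  expect_error(assessment_record("mobile", "c", "i", ans, schema = schema),
               "required item")
  expect_error(assessment_record("paper", "c", "i",
                                 start_time = Sys.time(),
                                 end_time = Sys.time() - 100), "precedes")
})

test_that("the summary page lists findings, referral advice and follow-up", {
  cs <- healthy_case()
  p <- classify_case(cs)
  plan <- build_plan(p, as.Date(cs$assessment_datetime, tz = "UTC"))
  txt <- summary_report(cs, p, plan)
  expect_match(txt, "No danger signs")
  expect_match(txt, "Follow-up visit: 2017-03-14")

  cs <- healthy_case(temperature = 39)
  p <- classify_case(cs)
  plan <- build_plan(p, as.Date(cs$assessment_datetime, tz = "UTC"))
  txt <- summary_report(cs, p, plan)
  expect_match(txt, "fever")
  expect_match(txt, "REFER")
  expect_no_match(txt, "Follow-up visit")

  cs <- healthy_case(birth_weight_g = 2300, current_weight_g = 2250, foot_length_mm = 70)
  p <- classify_case(cs)
  plan <- build_plan(p, as.Date(cs$assessment_datetime, tz = "UTC"))
  txt <- summary_report(cs, p, plan)
  expect_match(txt, "kangaroo mother care")
})
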