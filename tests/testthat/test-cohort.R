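test_that("cohort generation is deterministic in the seed", {
  a <- generate_cohort(cohort_spec(n_infants = 25, seed = 77))
  b <- generate_cohort(cohort_spec(n_infants = 25, seed = 77))
  expect_equal(cases_to_df(a$cases), cases_to_df(b$cases))
  c_ <- generate_cohort(cohort_spec(n_infants = 25, seed = 78))
  expect_false(identical(cases_to_df(a$cases), cases_to_df(c_$cases)))
})

test_that("generated measurements always reproduce the gold labels", {
  co <- generate_cohort(cohort_spec(n_infants = 300, seed = 41))
  cfg <- classification_config()
  for (i in seq_along(co$cases)) {
    p <- classify_case(co$cases[[i]], cfg)
    expect_identical(p$conditions, co$gold[[i]]$conditions)
  }
  # gold profiles are fully resolved apart from preterm without an LMP
  res <- vapply(co$gold, function(g) all(g$conditions != "na"), logical(1))
  expect_true(all(res))
})

test_that("cohort spec rejects contradictory prevalence settings", {
  expect_error(cohort_spec(prevalence = c(severe_weight_loss = 0.7,
                                          moderate_weight_loss = 0.5)),
               "exceed 1")
  expect_error(cohort_spec(prevalence = c(fever = 0.9, hypothermia = 0.2)), "exceed 1")
  expect_error(cohort_spec(prevalence = c(very_low_weight_lt1500 = 0.6,
                                          low_birth_weight = 0.3)), "cannot exceed")
  expect_error(cohort_spec(prevalence = c(nonsense = 0.5)), "unknown condition")
  expect_error(cohort_spec(n_infants = 0), ">= 1")
})

test_that("every CHW uses both methods under the crossover", {
  co <- generate_cohort(cohort_spec(n_infants = 85, seed = 9))
  sim <- simulate_assessments(co, em = error_model(seed = 10))
  used <- table(sim$assignments$chw_id, sim$assignments$method)
  expect_identical(nrow(used), 12L)
  expect_true(all(used > 0))
  # odd-id CHWs start mobile, even-id start paper
  first <- sim$assignments[!duplicated(sim$assignments$chw_id), ]
  odd <- as.integer(sub("chw", "", first$chw_id)) %% 2 == 1
  expect_true(all(first$method[odd] == "mobile"))
  expect_true(all(first$method[!odd] == "paper"))
})

test_that("a perfect error-free assessor is always correct and complete", {
  co <- generate_cohort(cohort_spec(n_infants = 20, seed = 13))
  cal <- calibrate_error_model()
  perfect <- error_model(
    sens = matrix(1, nrow(cal$sens), 2, dimnames = dimnames(cal$sens)),
    spec = matrix(1, nrow(cal$spec), 2, dimnames = dimnames(cal$spec)),
    chw_sd = 0,
    missingness = list(temp = 0, rr = 0, weight = 0, sign = 0,
                       recommendation = 0, weight_loss_calc = 0,
                       postnatal_age_calc = 0, ga_calc_given_lmp = 0),
    seed = 21)
  sim <- simulate_assessments(co, em = perfect)
  expect_true(all(sim$labeled$correct))
  aud <- audit_records(sim$records)
  expect_true(all(aud$full_assessment))
})

test_that("raising sensitivity never lowers the simulated correct proportion", {
  co <- generate_cohort(cohort_spec(n_infants = 60, seed = 19))
  cal <- calibrate_error_model()
  run_with_sens <- function(s) {
    sens <- cal$sens; sens["poor_feeding", ] <- s
    sim <- simulate_assessments(co, em = error_model(sens = sens, spec = cal$spec,
                                                     seed = 23))
    lab <- sim$labeled[sim$labeled$condition == "poor_feeding", ]
    mean(lab$correct[lab$gold_call])
  }
  props <- vapply(c(0.5, 0.7, 0.9, 0.99), run_with_sens, numeric(1))
  expect_true(all(diff(props) >= 0))
})

test_that("the design requires enough assessments for every CHW to cross over", {
  co <- generate_cohort(cohort_spec(n_infants = 5, seed = 2))
  expect_error(simulate_assessments(co, em = error_model(seed = 2,
                                                         assessments_per_infant = 2)),
               "design error")
})
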