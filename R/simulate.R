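flip_call <- function(x) switch(x, positive = "negative", negative = "positive", "na")

# assessor-call profile shaped like a classifier output, so the management
# rules can run on what the assessor believed
assessor_profile <- function(infant_id, calls, derived, config) {
  structure(list(
    infant_id = infant_id,
    conditions = calls,
    preterm = "na",
    any_danger_sign = any(calls[config$danger_sign_set] == "positive"),
    eligible = TRUE,
    derived = derived
  ), class = "condition_profile")
}

recommendations_from_plan <- function(plan) {
  recs <- character()
  if (plan$refer) {
    recs <- c(recs, paste("refer to facility:",
                          paste(gsub("_", " ", plan$referral_reasons), collapse = ", ")))
  }
  recs <- c(recs, gsub("_", " ", plan$counseling))
  if (!is.na(plan$follow_up_date)) {
    recs <- c(recs, paste("follow-up visit on", format(plan$follow_up_date)))
  }
  recs
}

#' Simulate a crossover method-comparison study
#'
#' Assigns each infant's assessments to CHWs in rotation. CHWs with odd ids
#' start on the mobile method and even ids on paper; after each block of
#' `block_size` assessments a CHW switches to the other method, so every
#' CHW uses both. Each condition call agrees with the gold label with
#' probability `sens` (gold positive) or `spec` (gold negative), shifted on
#' the log-odds scale by the CHW's random effect. On paper, fields go
#' unrecorded with the configured missingness and the conditions they
#' drive become unassessable; mobile records are produced through the form
#' engine, which cannot skip required items. Recommendations are generated
#' from the management rules applied to the *assessor's* calls (always at
#' least the follow-up date on mobile; written with probability
#' `1 - missingness$recommendation` on paper).
#'
#' Three independent RNG streams (error draws, missingness draws,
#' completion times) are derived from the model seed so changing one set
#' of parameters does not perturb unrelated draws.
#'
#' @param cohort Output of [generate_cohort()] (uses `cohort$cases`).
#' @param gold Named list of gold profiles (default `cohort$gold`).
#' @param em An [error_model()].
#' @param config A [classification_config()].
#' @param mgmt A [management_config()].
#' @return List with `records` (list of [assessment_record()]), `labeled`
#'   (one row per assessment x condition) and `assignments` (one row per
#'   assessment).
#' @export
simulate_assessments <- function(cohort, gold = cohort$gold,
                                 em = error_model(),
                                 config = classification_config(),
                                 mgmt = management_config(class_config = config)) {
  cases <- cohort$cases
  n_inf <- length(cases)
  n_assess <- n_inf * em$assessments_per_infant
  if (em$n_chws * 2L > n_assess) {
    stop("design error: too few assessments for every CHW to use both methods",
         call. = FALSE)
  }
  conds <- condition_names()
  nc <- length(conds)

  # stream 1: assessor error (CHW effects, then one uniform per call)
  draws <- with_seed(em$seed, {
    list(chw_effect = stats::rnorm(em$n_chws, 0, em$chw_sd),
         u = matrix(stats::runif(n_assess * nc), n_assess, nc))
  })
  # stream 2: paper-form missingness
  miss <- with_seed(em$seed + 1L, {
    ms <- em$missingness
    list(temp = stats::runif(n_assess) < ms$temp,
         rr = stats::runif(n_assess) < ms$rr,
         weight = stats::runif(n_assess) < ms$weight,
         sign = matrix(stats::runif(n_assess * nc) < ms$sign, n_assess, nc),
         rec = stats::runif(n_assess) < ms$recommendation,
         wl_calc = stats::runif(n_assess) < ms$weight_loss_calc,
         age_calc = stats::runif(n_assess) < ms$postnatal_age_calc,
         ga_calc = stats::runif(n_assess) < ms$ga_calc_given_lmp)
  })
  # stream 3: completion times (minutes)
  times <- with_seed(em$seed + 2L, {
    list(mobile = pmax(stats::rnorm(n_assess, 17.5, 10.8), 3),
         paper = pmax(stats::rnorm(n_assess, 23.6, 11.6), 3))
  })

  schema <- cncp_form_schema(config)
  chw_counter <- integer(em$n_chws)
  records <- vector("list", n_assess)
  labeled <- vector("list", n_assess)
  assignments <- vector("list", n_assess)

  for (j in seq_len(n_assess)) {
    inf_i <- ((j - 1L) %% n_inf) + 1L
    case <- cases[[inf_i]]
    g <- gold[[case$infant_id]]
    chw <- ((j - 1L) %% em$n_chws) + 1L
    chw_counter[chw] <- chw_counter[chw] + 1L
    start_mobile <- chw %% 2L == 1L
    block <- (chw_counter[chw] - 1L) %/% em$block_size
    mobile <- xor(block %% 2L == 1L, start_mobile)
    method <- if (mobile) "mobile" else "paper"
    chw_id <- sprintf("chw%02d", chw)

    # per-condition assessor calls
    calls <- stats::setNames(character(nc), conds)
    m_cond <- if (method == "paper") {
      c(fever = miss$temp[j], hypothermia = miss$temp[j],
        fast_breathing = miss$rr[j],
        low_birth_weight = miss$weight[j], small = miss$weight[j],
        very_low_weight_lt1500 = miss$weight[j],
        severe_weight_loss = miss$weight[j], moderate_weight_loss = miss$weight[j])
    } else c()
    for (k in seq_len(nc)) {
      cn <- conds[k]
      gk <- g$conditions[[cn]]
      unrecorded <- if (method == "paper") {
        if (cn %in% names(m_cond)) m_cond[[cn]] else miss$sign[j, k]
      } else FALSE
      if (gk == "na" || unrecorded) {
        calls[k] <- "na"
      } else {
        base <- if (gk == "positive") em$sens[cn, method] else em$spec[cn, method]
        pr <- stats::plogis(stats::qlogis(base) + draws$chw_effect[chw])
        calls[k] <- if (draws$u[j, k] < pr) gk else flip_call(gk)
      }
    }

    prof <- assessor_profile(case$infant_id, calls, g$derived, config)
    assess_date <- as.Date(case$assessment_datetime, tz = "UTC")
    plan <- build_plan(prof, assess_date, mgmt)
    recs <- recommendations_from_plan(plan)

    dur <- if (method == "mobile") times$mobile[j] else times$paper[j]
    start_time <- case$assessment_datetime
    end_time <- start_time + round(dur * 60)

    if (method == "mobile") {
      answers <- run_form(schema, mobile_answer_fun(case, calls))
      rec <- assessment_record("mobile", chw_id, case$infant_id, answers,
                               recommendations = recs,
                               start_time = start_time, end_time = end_time,
                               study_day = 2L, schema = schema)
    } else {
      answers <- paper_answers(case, calls, g,
                               temp_missing = miss$temp[j], rr_missing = miss$rr[j],
                               weight_missing = miss$weight[j],
                               wl_calc_missing = miss$wl_calc[j],
                               age_calc_missing = miss$age_calc[j],
                               ga_calc_missing = miss$ga_calc[j])
      rec <- assessment_record("paper", chw_id, case$infant_id, answers,
                               recommendations = if (miss$rec[j]) character() else recs,
                               start_time = start_time, end_time = end_time,
                               study_day = 2L)
    }
    records[[j]] <- rec
    labeled[[j]] <- data.frame(
      chw_id = chw_id, infant_id = case$infant_id, method = method,
      condition = conds, assessor_call = unname(calls),
      gold_call = unname(g$conditions[conds]) == "positive",
      correct = unname(calls != "na" & calls == g$conditions[conds]),
      stringsAsFactors = FALSE
    )
    assignments[[j]] <- data.frame(
      assessment = j, chw_id = chw_id, infant_id = case$infant_id,
      method = method, duration_min = dur, stringsAsFactors = FALSE
    )
  }
  list(records = records,
       labeled = do.call(rbind, labeled),
       assignments = do.call(rbind, assignments))
}

# answer function feeding the form engine from a case plus the simulated
# sign calls; measurements are entered as observed on the infant
mobile_answer_fun <- function(case, calls) {
  function(item, answers) {
    id <- item$id
    if (startsWith(id, "sign_")) {
      cn <- sub("^sign_", "", id)
      return(if (calls[[cn]] == "positive") "yes" else "no")
    }
    if (startsWith(id, "fi_")) {
      nm <- sub("^fi_", "", id)
      # item answers consistent with the composite call
      if (calls[["feeding_intolerance"]] == "positive") {
        return(if (nm == "frequent_vomiting") "yes" else case$feeding_intolerance[[nm]] %na% "no")
      }
      return("no")
    }
    if (startsWith(id, "bf_")) {
      nm <- sub("^bf_", "", id)
      if (calls[["breastfeeding_problems"]] == "positive") {
        return(if (nm == "five_plus_wet_diapers") "no" else case$breastfeeding[[nm]] %na% "yes")
      }
      return("yes")
    }
    switch(id,
      infant_id = case$infant_id,
      sex = case$sex,
      birth_datetime = case$birth_datetime,
      assessment_datetime = case$assessment_datetime,
      lmp_known = if (is.na(case$lmp_date)) "no" else "yes",
      lmp_date = case$lmp_date,
      birth_weight_known = if (is.na(case$birth_weight_g)) "no" else "yes",
      birth_weight_g = case$birth_weight_g,
      current_weight_g = case$current_weight_g,
      foot_length_mm = case$foot_length_mm,
      temperature_c = if (is.na(case$temperature)) NA else
        normalize_temperature(case$temperature, case$temperature_unit),
      breath_count_60s = case$breath_count_60s,
      kmc_counseled = "yes",
      skin_to_skin_hours = 6,
      stop("no simulated answer for item '", id, "'")
    )
  }
}

`%na%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

paper_answers <- function(case, calls, gold, temp_missing, rr_missing,
                          weight_missing, wl_calc_missing, age_calc_missing,
                          ga_calc_missing) {
  ans <- list(
    infant_id = case$infant_id,
    sex = case$sex,
    birth_datetime = format(case$birth_datetime, "%Y-%m-%dT%H:%M"),
    assessment_datetime = format(case$assessment_datetime, "%Y-%m-%dT%H:%M")
  )
  for (nm in sign_names()) {
    cl <- calls[[nm]]
    ans[[paste0("sign_", nm)]] <- switch(cl, positive = "yes", negative = "no", NA)
  }
  fi_na <- calls[["feeding_intolerance"]] == "na"
  for (nm in feeding_intolerance_items()) {
    ans[[paste0("fi_", nm)]] <- if (fi_na) NA else case$feeding_intolerance[[nm]]
  }
  bf_na <- calls[["breastfeeding_problems"]] == "na"
  for (nm in breastfeeding_items()) {
    ans[[paste0("bf_", nm)]] <- if (bf_na) NA else case$breastfeeding[[nm]]
  }
  ans$temperature_c <- if (temp_missing || is.na(case$temperature)) NA else
    normalize_temperature(case$temperature, case$temperature_unit)
  ans$breath_count_60s <- if (rr_missing) NA else case$breath_count_60s
  ans$birth_weight_g <- if (weight_missing) NA else case$birth_weight_g
  ans$current_weight_g <- if (weight_missing) NA else case$current_weight_g
  ans$foot_length_mm <- if (weight_missing) NA else case$foot_length_mm
  ans$weight_change_pct <- if (weight_missing || wl_calc_missing) NA else
    round_half_up(gold$derived$weight_change_percent, 1)
  ans$postnatal_age_days <- if (age_calc_missing) NA else
    gold$derived$postnatal_age_days
  lmp_rec <- !is.na(case$lmp_date)
  ans$lmp_date <- if (lmp_rec) format(case$lmp_date) else NA
  ans$ga_weeks <- if (lmp_rec && !ga_calc_missing) {
    round_half_up(gold$derived$gestational_age_weeks, 1)
  } else NA
  ans
}
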