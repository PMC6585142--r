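with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic newborn cohort
#'
#' Default condition prevalences are the expert-classification rates of the
#' published study's paper-arm cohort (e.g. poor feeding 52/84, severe
#' weight loss 21/84, fever 13/84, hypothermia 5/84, fast breathing 18/84,
#' breastfeeding problems 32/84); postnatal age is truncated-normal with
#' mean 6.5 and SD 6.7 days on \[0, 27\]; gestational age is normal with
#' mean 40.1 and SD 3.2 weeks; 31% of infants are female. In the generated
#' cohort *small* coincides with low birth weight (short feet are given
#' exactly to low-birth-weight infants), matching the published cohort
#' where the two rates are identical.
#'
#' @param n_infants Number of infants.
#' @param prevalence Named numeric vector of condition prevalences;
#'   overrides merge into the published defaults. `small` follows
#'   `low_birth_weight` and cannot be set independently.
#' @param age_mean,age_sd,age_range Postnatal-age distribution (days).
#' @param ga_mean_weeks,ga_sd_weeks Gestational-age distribution.
#' @param p_female Proportion female.
#' @param lmp_recorded_prob Probability the mother recalls her LMP date
#'   (the published mobile arm recorded an LMP for about a third of
#'   assessments).
#' @param seed RNG seed for this cohort stream.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_infants = 100,
                        prevalence = NULL,
                        age_mean = 6.5, age_sd = 6.7, age_range = c(0, 27),
                        ga_mean_weeks = 40.1, ga_sd_weeks = 3.2,
                        p_female = 0.31,
                        lmp_recorded_prob = 0.33,
                        seed = 20170301) {
  prev <- published_prevalence_counts()
  defaults <- stats::setNames(prev$expert_pos_paper / prev$n_paper, prev$condition)
  if (!is.null(prevalence)) {
    prevalence <- unlist(prevalence)
    bad <- setdiff(names(prevalence), names(defaults))
    if (length(bad)) stop("unknown condition(s) in prevalence: ", paste(bad, collapse = ", "))
    defaults[names(prevalence)] <- prevalence
  }
  defaults["small"] <- defaults["low_birth_weight"]
  if (n_infants < 1) stop("n_infants must be >= 1", call. = FALSE)
  if (any(defaults < 0 | defaults > 1)) stop("prevalences must lie in [0, 1]", call. = FALSE)
  if (defaults["severe_weight_loss"] + defaults["moderate_weight_loss"] > 1) {
    stop("severe + moderate weight-loss prevalences exceed 1", call. = FALSE)
  }
  if (defaults["fever"] + defaults["hypothermia"] > 1) {
    stop("fever + hypothermia prevalences exceed 1", call. = FALSE)
  }
  if (defaults["very_low_weight_lt1500"] > defaults["low_birth_weight"]) {
    stop("very-low-weight prevalence cannot exceed low-birth-weight prevalence",
         call. = FALSE)
  }
  structure(list(
    n_infants = as.integer(n_infants), prevalence = defaults,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    ga_mean_weeks = ga_mean_weeks, ga_sd_weeks = ga_sd_weeks,
    p_female = p_female, lmp_recorded_prob = lmp_recorded_prob,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Generate a synthetic cohort with known gold labels
#'
#' Draws each infant's gold condition labels from the configured prevalences and
#' then samples raw measurements from the matching side of each
#' classification threshold, so that running the classifier on the
#' generated case reproduces the gold profile *exactly* (this identity is
#' re-checked for every infant before returning). Measurement windows sit
#' a safety margin away from band edges so gram- and decimal-rounding can
#' never flip a label. Fever and hypothermia are drawn as one mutually
#' exclusive temperature category; weight-loss severity bands follow the
#' infant's size; very-low-weight infants are a sub-sample of the
#' low-birth-weight group.
#'
#' @param spec A [cohort_spec()].
#' @param config The [classification_config()] whose thresholds the
#'   measurements must respect.
#' @return List with `cases` (list of [infant_case()]) and `gold` (named
#'   list of `condition_profile`, indexed by infant id).
#' @export
generate_cohort <- function(spec = cohort_spec(), config = classification_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  pv <- spec$prevalence
  with_seed(spec$seed, {
    cases <- vector("list", spec$n_infants)
    gold <- vector("list", spec$n_infants)
    base_assess <- as.POSIXct("2017-03-15 08:00", tz = "UTC")
    for (i in seq_len(spec$n_infants)) {
      id <- sprintf("syn-%04d", i)
      assess <- base_assess + (i - 1) * 600
      age_days <- floor(rtruncnorm1(spec$age_mean, spec$age_sd,
                                    spec$age_range[1], spec$age_range[2] + 0.999))
      age_days <- min(max(age_days, spec$age_range[1]), spec$age_range[2])
      birth <- assess - (age_days + stats::runif(1, 0.01, 0.95)) * 86400

      small <- stats::runif(1) < pv[["low_birth_weight"]]
      vlw <- small && stats::runif(1) < pv[["very_low_weight_lt1500"]] / pv[["low_birth_weight"]]
      bw <- if (vlw) 10 * sample(100:149, 1)
            else if (small) 10 * sample(190:245, 1)
            else 10 * sample(255:400, 1)
      foot <- if (small) sample(62:73, 1) else sample(74:90, 1)

      u <- stats::runif(1)
      wl_cat <- if (u < pv[["severe_weight_loss"]]) "severe"
                else if (u < pv[["severe_weight_loss"]] + pv[["moderate_weight_loss"]]) "moderate"
                else "none"
      band <- if (small) config$wl_small else config$wl_nonsmall
      loss <- switch(wl_cat,
        severe = stats::runif(1, band[2] + 0.5, band[2] + 5),
        moderate = stats::runif(1, band[1] + 0.3, band[2] - 0.3),
        none = stats::runif(1, -5, band[1] - 0.5))
      cw <- round(bw * (1 - loss / 100))

      u <- stats::runif(1)
      temp <- if (u < pv[["hypothermia"]]) sample(seq(30, config$hypothermia_C - 0.1, 0.1), 1)
              else if (u < pv[["hypothermia"]] + pv[["fever"]]) sample(seq(config$fever_C + 0.1, 40.5, 0.1), 1)
              else sample(seq(config$hypothermia_C, config$fever_C, 0.1), 1)
      rr <- if (stats::runif(1) < pv[["fast_breathing"]]) sample(61:90, 1) else sample(30:60, 1)

      lmp <- if (stats::runif(1) < spec$lmp_recorded_prob) {
        ga_days <- round(7 * rtruncnorm1(spec$ga_mean_weeks, spec$ga_sd_weeks, 28, 44))
        as.Date(birth, tz = "UTC") - ga_days
      } else NA

      signs <- stats::setNames(ifelse(
        stats::runif(length(sign_names())) < pv[sign_names()], "yes", "no"),
        sign_names())

      draw_items <- function(items, p_cond, problem, clear, p_item = 0.4) {
        if (stats::runif(1) < p_cond) {
          v <- ifelse(stats::runif(length(items)) < p_item, problem, clear)
          if (!any(v == problem)) v[sample(length(items), 1)] <- problem
        } else {
          v <- rep(clear, length(items))
        }
        stats::setNames(v, items)
      }
      fi <- draw_items(feeding_intolerance_items(), pv[["feeding_intolerance"]], "yes", "no")
      bf <- draw_items(breastfeeding_items(), pv[["breastfeeding_problems"]], "no", "yes", 0.35)

      case <- infant_case(
        infant_id = id,
        sex = if (stats::runif(1) < spec$p_female) "female" else "male",
        birth_datetime = birth, assessment_datetime = assess,
        lmp_date = lmp, birth_weight_g = bw, current_weight_g = cw,
        foot_length_mm = foot, temperature = temp, temperature_unit = "C",
        breath_count_60s = rr, signs = signs,
        feeding_intolerance = fi, breastfeeding = bf
      )
      prof <- classify_case(case, config)

      # the generated measurements must reproduce the drawn labels exactly
      intended <- c(
        low_birth_weight = small, small = small, very_low_weight_lt1500 = vlw,
        severe_weight_loss = wl_cat == "severe",
        moderate_weight_loss = wl_cat == "moderate"
      )
      got <- prof$conditions[names(intended)] == "positive"
      if (!all(got == intended)) {
        stop("internal error: generated measurements contradict drawn labels for ", id)
      }
      cases[[i]] <- case
      gold[[i]] <- prof
    }
    names(gold) <- vapply(cases, `[[`, character(1), "infant_id")
    list(cases = cases, gold = gold)
  })
}
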