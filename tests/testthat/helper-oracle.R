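# Brute-force reference classifier, coded independently of the package's
# rule engine: straight-line threshold checks per condition, no shared
# helpers beyond the documented definitions.
oracle_classify <- function(case, config = classification_config()) {
  r1 <- function(x) floor(x * 10 + 0.5) / 10  # half-up to one decimal

  tempC <- NA_real_
  if (!is.na(case$temperature)) {
    tempC <- if (case$temperature_unit == "F") r1((case$temperature - 32) * 5 / 9)
             else r1(case$temperature)
  }
  ga <- NA_real_
  if (!is.na(case$lmp_date)) {
    ga <- as.numeric(as.Date(case$birth_datetime, tz = "UTC") - case$lmp_date) / 7
  }
  bw <- case$birth_weight_g; cw <- case$current_weight_g; foot <- case$foot_length_mm
  rr <- case$breath_count_60s

  tri <- function(x) if (is.na(x)) "na" else if (x) "positive" else "negative"

  out <- c()
  out["low_birth_weight"] <- tri(if (is.na(bw)) NA else bw < config$lbw_threshold_g)
  small_crit <- c(if (!is.na(bw)) bw < config$lbw_threshold_g,
                  if (!is.na(foot)) foot < config$foot_length_threshold_mm)
  if (config$small_definition == "weight_or_foot_or_preterm" && !is.na(ga)) {
    small_crit <- c(small_crit, ga < config$preterm_weeks)
  }
  small <- if (length(small_crit) == 0) NA else any(small_crit)
  out["small"] <- tri(small)
  out["very_low_weight_lt1500"] <- tri(
    if (is.na(bw) && is.na(cw)) NA
    else isTRUE(bw < config$very_low_weight_g) || isTRUE(cw < config$very_low_weight_g))

  if (is.na(bw) || is.na(cw)) {
    out["severe_weight_loss"] <- "na"; out["moderate_weight_loss"] <- "na"
  } else {
    loss <- -100 * (cw - bw) / bw
    use_small <- if (is.na(small)) !config$nonsmall_bands_when_size_unknown else small
    lo <- if (use_small) config$wl_small[1] else config$wl_nonsmall[1]
    hi <- if (use_small) config$wl_small[2] else config$wl_nonsmall[2]
    out["severe_weight_loss"] <- if (loss > hi) "positive" else "negative"
    out["moderate_weight_loss"] <- if (loss >= lo && loss <= hi) "positive" else "negative"
  }

  out["fever"] <- tri(if (is.na(tempC)) NA else tempC > config$fever_C)
  out["hypothermia"] <- tri(if (is.na(tempC)) NA else tempC < config$hypothermia_C)
  out["fast_breathing"] <- tri(if (is.na(rr)) NA else rr > config$fast_breathing_bpm)

  for (nm in c("poor_movement", "convulsion_history", "poor_feeding",
               "severe_chest_indrawing", "umbilicus_red_or_pus", "skin_pustules",
               "jaundice_soles_or_body", "eye_infection")) {
    v <- case$signs[[nm]]
    out[nm] <- if (v == "yes") "positive" else if (v == "no") "negative" else "na"
  }

  fi <- case$feeding_intolerance
  out["feeding_intolerance"] <- if (any(fi == "yes")) "positive"
    else if (any(fi == "na")) "na" else "negative"
  bf <- case$breastfeeding
  out["breastfeeding_problems"] <- if (any(bf == "no")) "positive"
    else if (any(bf == "na")) "na" else "negative"

  attr(out, "preterm") <- tri(if (is.na(ga)) NA else ga < config$preterm_weeks)
  attr(out, "any_danger_sign") <- any(out[config$danger_sign_set] == "positive")
  out
}

# Random valid case exercising missing fields, both units, and all
# tri-state codes.
random_valid_case <- function(i = 1) {
  maybe <- function(p, value) if (runif(1) < p) NA else value
  birth <- as.POSIXct("2017-03-01 06:00", tz = "UTC") + runif(1, 0, 20) * 86400
  assess <- birth + runif(1, 0.1, 27.5) * 86400
  use_f <- runif(1) < 0.3
  tri_draw <- function(n) sample(c("yes", "no", "na"), n, replace = TRUE,
                                 prob = c(0.25, 0.55, 0.2))
  infant_case(
    infant_id = sprintf("rnd-%05d", i),
    sex = sample(c("female", "male", "unrecorded"), 1),
    birth_datetime = birth,
    assessment_datetime = assess,
    lmp_date = maybe(0.5, as.Date(birth, tz = "UTC") - sample(150:320, 1)),
    birth_weight_g = maybe(0.15, round(runif(1, 300, 7000))),
    current_weight_g = maybe(0.15, round(runif(1, 300, 7000))),
    foot_length_mm = maybe(0.25, sample(40:110, 1)),
    temperature = if (use_f) maybe(0.15, round(runif(1, 86, 106), 1))
                  else maybe(0.15, round(runif(1, 30, 41), 1)),
    temperature_unit = if (use_f) "F" else "C",
    breath_count_60s = maybe(0.2, sample(0:90, 1)),
    signs = setNames(tri_draw(length(sign_names())), sign_names()),
    feeding_intolerance = setNames(tri_draw(5), feeding_intolerance_items()),
    breastfeeding = setNames(tri_draw(5), breastfeeding_items())
  )
}

# simple healthy term baseline case used across tests
healthy_case <- function(id = "base", ...) {
  defaults <- list(
    infant_id = id, sex = "female",
    birth_datetime = as.POSIXct("2017-03-01 08:00", tz = "UTC"),
    assessment_datetime = as.POSIXct("2017-03-07 10:00", tz = "UTC"),
    lmp_date = as.Date("2016-06-01"),
    birth_weight_g = 3200, current_weight_g = 3150,
    foot_length_mm = 80, temperature = 37.0, temperature_unit = "C",
    breath_count_60s = 45,
    signs = setNames(rep("no", length(sign_names())), sign_names()),
    feeding_intolerance = setNames(rep("no", 5), feeding_intolerance_items()),
    breastfeeding = setNames(rep("yes", 5), breastfeeding_items())
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(infant_case, args)
}
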