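#' Classification thresholds and rule settings
#'
#' All thresholds live here rather than at call sites so a deployment can
#' retune them from a config file without code changes. Defaults follow the
#' national newborn-care guideline thresholds: low birth weight `< 2500` g,
#' short foot `< 74` mm, very low weight `< 1500` g, preterm `< 37.0` weeks,
#' fast breathing `> 60` breaths/min, fever `> 38.0` degC, hypothermia
#' `< 35.5` degC. Weight-loss bands are closed for the moderate category and
#' strict for severe: small infants moderate at 8-10% loss and severe over
#' 10%; non-small infants moderate at 10-15% and severe over 15%.
#'
#' @param lbw_threshold_g Low-birth-weight cut-off, grams.
#' @param foot_length_threshold_mm Short-foot cut-off, millimetres.
#' @param very_low_weight_g Very-low-weight cut-off, grams (birth or current).
#' @param preterm_weeks Preterm cut-off in completed weeks.
#' @param small_definition `"weight_or_foot"` (default, the definition the
#'   accuracy analyses use) or `"weight_or_foot_or_preterm"`.
#' @param wl_small,wl_nonsmall Length-2 numeric: moderate band \[lo, hi\] in
#'   percent loss; loss above `hi` is severe.
#' @param fast_breathing_bpm,fever_C,hypothermia_C Vital-sign thresholds
#'   (all strict inequalities).
#' @param nonsmall_bands_when_size_unknown When size cannot be resolved the
#'   (wider) non-small weight-loss bands are used; set `FALSE` to use the
#'   small-infant bands instead.
#' @param danger_sign_set Condition names whose positives trigger
#'   `any_danger_sign`.
#' @return A list of class `classification_config`.
#' @export
classification_config <- function(lbw_threshold_g = 2500,
                                  foot_length_threshold_mm = 74,
                                  very_low_weight_g = 1500,
                                  preterm_weeks = 37.0,
                                  small_definition = c("weight_or_foot",
                                                       "weight_or_foot_or_preterm"),
                                  wl_small = c(8, 10),
                                  wl_nonsmall = c(10, 15),
                                  fast_breathing_bpm = 60,
                                  fever_C = 38.0,
                                  hypothermia_C = 35.5,
                                  nonsmall_bands_when_size_unknown = TRUE,
                                  danger_sign_set = NULL) {
  small_definition <- match.arg(small_definition)
  if (is.null(danger_sign_set)) {
    danger_sign_set <- c(
      "poor_movement", "convulsion_history", "poor_feeding",
      "severe_chest_indrawing", "fast_breathing", "umbilicus_red_or_pus",
      "skin_pustules", "jaundice_soles_or_body", "eye_infection",
      "fever", "hypothermia", "severe_weight_loss",
      "very_low_weight_lt1500", "feeding_intolerance"
    )
  }
  cfg <- list(
    lbw_threshold_g = lbw_threshold_g,
    foot_length_threshold_mm = foot_length_threshold_mm,
    very_low_weight_g = very_low_weight_g,
    preterm_weeks = preterm_weeks,
    small_definition = small_definition,
    wl_small = wl_small,
    wl_nonsmall = wl_nonsmall,
    fast_breathing_bpm = fast_breathing_bpm,
    fever_C = fever_C,
    hypothermia_C = hypothermia_C,
    nonsmall_bands_when_size_unknown = nonsmall_bands_when_size_unknown,
    danger_sign_set = danger_sign_set
  )
  thr <- c(lbw_threshold_g, foot_length_threshold_mm, very_low_weight_g,
           preterm_weeks, fast_breathing_bpm, fever_C, hypothermia_C)
  if (any(thr <= 0)) stop("all thresholds must be positive", call. = FALSE)
  if (wl_small[1] > wl_small[2] || wl_nonsmall[1] > wl_nonsmall[2]) {
    stop("weight-loss band edges must be ordered", call. = FALSE)
  }
  bad <- setdiff(danger_sign_set, condition_names())
  if (length(bad)) stop("unknown danger-sign condition(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "classification_config")
}

#' Case-management rule tables
#'
#' The referral rule table, small-infant referral additions, the counseling
#' mapping and the follow-up offsets. The published description of the app
#' names the counseling items and states that referral follows from any
#' single danger sign with lower thresholds for small infants, but does not
#' print the full mapping; the defaults here are explicit, documented
#' stand-ins that can be overridden wholesale from a config file.
#'
#' Default referral rules: every condition in the danger-sign set refers;
#' additionally a small infant with moderate weight loss or breastfeeding
#' problems refers. Default counseling: small or hypothermic infants get
#' kangaroo mother care and thermal care; small infants with breastfeeding
#' problems also get small-infant breastfeeding advice and cup feeding; any
#' weight loss category or poor feeding adds increased feeding frequency;
#' breastfeeding problems add general breastfeeding support; an infected
#' umbilicus adds cord-care advice. Follow-up: referred infants get no
#' scheduled follow-up; small infants or any moderate condition at +2 days;
#' otherwise +7 days.
#'
#' @param referral_conditions Conditions that refer when positive (defaults
#'   to the classification config's danger-sign set).
#' @param small_referral_additions Conditions that refer when positive *and*
#'   the infant is small.
#' @param counseling_rules List of rules, each
#'   `list(when = <predicate name>, items = <counseling items>)`.
#' @param follow_up_small_days,follow_up_default_days Follow-up offsets.
#' @param class_config The [classification_config()] supplying the
#'   danger-sign set default.
#' @return A list of class `management_config`.
#' @export
management_config <- function(referral_conditions = NULL,
                              small_referral_additions = c("moderate_weight_loss",
                                                           "breastfeeding_problems"),
                              counseling_rules = NULL,
                              follow_up_small_days = 2,
                              follow_up_default_days = 7,
                              class_config = classification_config()) {
  if (is.null(referral_conditions)) {
    referral_conditions <- class_config$danger_sign_set
  }
  if (is.null(counseling_rules)) {
    counseling_rules <- list(
      list(when = "small_or_hypothermia",
           items = c("kangaroo_mother_care", "thermal_care")),
      list(when = "small_and_breastfeeding_problems",
           items = c("small_infant_breastfeeding_advice", "cup_feeding")),
      list(when = "weight_loss_or_poor_feeding",
           items = "increase_feeding_frequency"),
      list(when = "breastfeeding_problems",
           items = "general_breastfeeding_support"),
      list(when = "umbilicus_red_or_pus",
           items = "cord_care_advice")
    )
  }
  structure(list(
    referral_conditions = referral_conditions,
    small_referral_additions = small_referral_additions,
    counseling_rules = counseling_rules,
    follow_up_small_days = follow_up_small_days,
    follow_up_default_days = follow_up_default_days
  ), class = "management_config")
}

#' Counseling item vocabulary
#' @return Character vector of all counseling item codes.
#' @export
counseling_item_names <- function() {
  c("kangaroo_mother_care", "cup_feeding", "increase_feeding_frequency",
    "thermal_care", "small_infant_breastfeeding_advice",
    "general_breastfeeding_support", "cord_care_advice")
}

#' Read a study configuration file
#'
#' A YAML file with optional sections `classification`, `management`,
#' `cohort`, `error_model` and `seed`; fields override the documented
#' defaults of [classification_config()], [management_config()],
#' [cohort_spec()] and [error_model()].
#'
#' @param path YAML file path.
#' @return A list of class `run_config` with the four config objects plus
#'   `seed`.
#' @export
read_run_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  build <- function(fun, section) {
    args <- raw[[section]] %||% list()
    do.call(fun, args)
  }
  cc <- build(classification_config, "classification")
  structure(list(
    classification = cc,
    management = {
      args <- raw[["management"]] %||% list()
      args$class_config <- cc
      do.call(management_config, args)
    },
    cohort = build(cohort_spec, "cohort"),
    error_model = build(error_model, "error_model"),
    seed = raw$seed %||% 1L
  ), class = "run_config")
}
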