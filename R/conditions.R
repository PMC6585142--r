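#' Condition and sign vocabularies
#'
#' The classifier produces a tri-state call (`"positive"`, `"negative"`,
#' `"na"`) for each of 18 newborn conditions. Eight of these are direct
#' observational danger signs, five are threshold-based size/weight
#' conditions, three are vital-sign thresholds, and two are composites over
#' five-item checklists.
#'
#' @return Character vector of names.
#' @export
condition_names <- function() {
  c(
    "low_birth_weight", "small", "very_low_weight_lt1500",
    "severe_weight_loss", "moderate_weight_loss",
    "poor_movement", "convulsion_history", "poor_feeding",
    "severe_chest_indrawing", "fast_breathing",
    "umbilicus_red_or_pus", "skin_pustules", "jaundice_soles_or_body",
    "eye_infection", "fever", "hypothermia",
    "feeding_intolerance", "breastfeeding_problems"
  )
}

#' @rdname condition_names
#' @export
sign_names <- function() {
  c(
    "poor_movement", "convulsion_history", "poor_feeding",
    "severe_chest_indrawing", "umbilicus_red_or_pus", "skin_pustules",
    "jaundice_soles_or_body", "eye_infection"
  )
}

#' @rdname condition_names
#' @export
feeding_intolerance_items <- function() {
  c(
    "chokes_on_feeds", "turns_blue_or_pale_feeding", "frequent_vomiting",
    "distended_or_tender_abdomen", "bloody_stools"
  )
}

#' Breastfeeding checklist items
#'
#' Answers are favourable when `"yes"`: the infant wakes easily for feeds,
#' feeds at least ten minutes per side, sleeps comfortably between feeds, has
#' five or more wet diapers per day, and the mother's breasts have softened
#' after feeds. A `"no"` on any item flags a breastfeeding problem.
#'
#' @return Character vector of item names.
#' @export
breastfeeding_items <- function() {
  c(
    "wakes_easily_for_feeds", "feeds_10min_per_side",
    "sleeps_comfortably_between_feeds", "five_plus_wet_diapers",
    "mothers_breasts_softened"
  )
}

# Tri-state codes used throughout: observations are "yes"/"no"/"na",
# condition calls are "positive"/"negative"/"na".
TRISTATE_OBS <- c("yes", "no", "na")
TRISTATE_CALL <- c("positive", "negative", "na")
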