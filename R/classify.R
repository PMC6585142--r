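# Tri-state helpers over condition calls ------------------------------------

call_from_logical <- function(x) {
  if (is.na(x)) "na" else if (x) "positive" else "negative"
}

#' Classify infant size status
#'
#' Low birth weight is birth weight under the configured cut-off; *small*
#' combines low birth weight with short foot length (and, under the
#' alternate definition, prematurity); very low weight fires when either
#' the birth or the current weight falls under 1500 g. A criterion with a
#' missing input is skipped: small is positive as soon as any available
#' criterion fires, negative when all available criteria clear, and `na`
#' only when no criterion is evaluable. In particular small is never `na`
#' when a birth weight is present.
#'
#' @param case An [infant_case()].
#' @param derived Its [derive_measures()] output.
#' @param config A [classification_config()].
#' @return Named character vector of calls for `low_birth_weight`, `small`,
#'   `very_low_weight_lt1500` and `preterm`.
#' @export
classify_size <- function(case, derived, config = classification_config()) {
  bw <- case$birth_weight_g
  cw <- case$current_weight_g
  foot <- case$foot_length_mm
  ga <- derived$gestational_age_weeks

  lbw <- if (is.na(bw)) NA else bw < config$lbw_threshold_g
  short_foot <- if (is.na(foot)) NA else foot < config$foot_length_threshold_mm
  preterm <- if (is.na(ga)) NA else ga < config$preterm_weeks

  crit <- c(lbw, short_foot)
  if (config$small_definition == "weight_or_foot_or_preterm") crit <- c(crit, preterm)
  # positive as soon as any evaluable criterion fires; na only when none is
  # evaluable; otherwise resolved negative
  small <- if (any(crit %in% TRUE)) TRUE else if (all(is.na(crit))) NA else FALSE

  vlw_in <- c(bw, cw)
  vlw <- if (all(is.na(vlw_in))) NA else any(vlw_in < config$very_low_weight_g, na.rm = TRUE)

  c(low_birth_weight = call_from_logical(lbw),
    small = call_from_logical(small),
    very_low_weight_lt1500 = call_from_logical(vlw),
    preterm = call_from_logical(preterm))
}

#' Categorize percent weight change into none / moderate / severe loss
#'
#' Bands depend on infant size: small infants are moderate at 8-10% loss
#' and severe above 10%; non-small infants are moderate at 10-15% and
#' severe above 15%. The moderate band is closed and severe strict, so a
#' loss of exactly 10% (small) or 15% (non-small) is moderate. Weight gain
#' is never loss. When size is unresolved the non-small bands apply by
#' default (configurable).
#'
#' @param percent Signed percent change (negative = loss).
#' @param small `TRUE`, `FALSE` or `NA` (unresolved size).
#' @param config A [classification_config()].
#' @return `"none"`, `"moderate"` or `"severe"`.
#' @export
classify_weight_loss <- function(percent, small, config = classification_config()) {
  stopifnot_scalar_number(percent, "percent")
  if (is.na(small)) {
    small <- !config$nonsmall_bands_when_size_unknown
  }
  band <- if (small) config$wl_small else config$wl_nonsmall
  loss <- -percent
  if (loss > band[2]) "severe"
  else if (loss >= band[1] && loss <= band[2]) "moderate"
  else "none"
}

#' Classify vital signs
#'
#' Fever is temperature strictly above 38.0 degC, hypothermia strictly
#' below 35.5 degC, fast breathing strictly above 60 breaths/min. A missing
#' measurement yields `na` for the conditions it drives.
#'
#' @param temperature_C Celsius temperature or `NA`.
#' @param respiratory_rate_bpm Breaths per minute or `NA`.
#' @param config A [classification_config()].
#' @return Named calls for `fever`, `hypothermia`, `fast_breathing`.
#' @export
classify_vitals <- function(temperature_C, respiratory_rate_bpm,
                            config = classification_config()) {
  fever <- if (is.na(temperature_C)) NA else temperature_C > config$fever_C
  hypo <- if (is.na(temperature_C)) NA else temperature_C < config$hypothermia_C
  fast <- if (is.na(respiratory_rate_bpm)) NA else respiratory_rate_bpm > config$fast_breathing_bpm
  c(fever = call_from_logical(fever),
    hypothermia = call_from_logical(hypo),
    fast_breathing = call_from_logical(fast))
}

# Composite over tri-state items: positive if any item indicates a problem,
# negative only when every item is resolved and clear, else na.
composite_call <- function(items, problem_code) {
  if (any(items == problem_code)) "positive"
  else if (any(items == "na")) "na"
  else "negative"
}

#' Classify feeding conditions
#'
#' Feeding intolerance fires on at least one of: chokes on feeds, turns
#' blue or pale when feeding, frequent vomiting, distended or tender
#' abdomen, bloody stools. Breastfeeding problems fire on at least one
#' unfavourable (`"no"`) answer among the five breastfeeding checklist
#' items. Either composite is resolved negative only when all five items
#' are answered and clear. `poor_feeding` is the direct observation sign
#' copied through.
#'
#' @param case An [infant_case()].
#' @return Named calls for `feeding_intolerance`, `breastfeeding_problems`,
#'   `poor_feeding`.
#' @export
classify_feeding <- function(case) {
  c(feeding_intolerance = composite_call(case$feeding_intolerance, "yes"),
    breastfeeding_problems = composite_call(case$breastfeeding, "no"),
    poor_feeding = sign_to_call(case$signs[["poor_feeding"]]))
}

sign_to_call <- function(obs) {
  switch(obs, yes = "positive", no = "negative", "na")
}

#' Classify a newborn case against all conditions
#'
#' The full diagnostic engine: computes the derived measures, applies the
#' size, weight-loss, vital-sign and feeding classifiers, copies the direct
#' observation signs through (`yes` to positive, `no` to negative, `na`
#' unchanged), and derives `any_danger_sign` as an OR over the configured
#' danger-sign subset (a sign contributes only when positive). The result
#' is deterministic and total on validated cases.
#'
#' @param case An [infant_case()].
#' @param config A [classification_config()].
#' @param check When `TRUE` (default), validation errors abort.
#' @return A list of class `condition_profile`: `infant_id`, `conditions`
#'   (named calls over [condition_names()]), `preterm`, `any_danger_sign`,
#'   `eligible`, and the `derived` measures.
#' @export
classify_case <- function(case, config = classification_config(), check = TRUE) {
  if (check) {
    v <- validate_case(case)
    if (!v$valid) {
      stop("invalid case ", case$infant_id, ": ",
           paste(v$errors$message, collapse = "; "), call. = FALSE)
    }
  }
  derived <- derive_measures(case)
  size <- classify_size(case, derived, config)
  vitals <- classify_vitals(derived$temperature_C, derived$respiratory_rate_bpm, config)
  feeding <- classify_feeding(case)

  small_lgl <- switch(size[["small"]], positive = TRUE, negative = FALSE, NA)
  wl <- if (is.na(derived$weight_change_percent)) {
    c(severe_weight_loss = "na", moderate_weight_loss = "na")
  } else {
    cat_ <- classify_weight_loss(derived$weight_change_percent, small_lgl, config)
    c(severe_weight_loss = if (cat_ == "severe") "positive" else "negative",
      moderate_weight_loss = if (cat_ == "moderate") "positive" else "negative")
  }

  conds <- stats::setNames(rep("na", length(condition_names())), condition_names())
  conds[names(size)[names(size) != "preterm"]] <- size[names(size) != "preterm"]
  conds[names(wl)] <- wl
  conds[names(vitals)] <- vitals
  conds[names(feeding)] <- feeding
  for (nm in setdiff(sign_names(), "poor_feeding")) {
    conds[[nm]] <- sign_to_call(case$signs[[nm]])
  }

  any_ds <- any(conds[config$danger_sign_set] == "positive")
  structure(list(
    infant_id = case$infant_id,
    conditions = conds,
    preterm = size[["preterm"]],
    any_danger_sign = any_ds,
    eligible = derived$eligible,
    derived = derived
  ), class = "condition_profile")
}

#' @export
print.condition_profile <- function(x, ...) {
  pos <- names(x$conditions)[x$conditions == "positive"]
  na_ <- names(x$conditions)[x$conditions == "na"]
  cat("<condition_profile>", x$infant_id, "\n")
  cat("  positive:", if (length(pos)) paste(pos, collapse = ", ") else "none", "\n")
  if (length(na_)) cat("  not assessable:", paste(na_, collapse = ", "), "\n")
  cat("  preterm:", x$preterm,
      " any_danger_sign:", x$any_danger_sign,
      " eligible:", x$eligible, "\n")
  invisible(x)
}

#' Classify a list of cases
#'
#' @param cases List of [infant_case()].
#' @inheritParams classify_case
#' @return List of `condition_profile`.
#' @export
classify_cohort <- function(cases, config = classification_config(), check = TRUE) {
  lapply(cases, classify_case, config = config, check = check)
}
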