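#' Construct a single newborn assessment case
#'
#' An `infant_case` holds the raw observations from one assessment encounter
#' of one newborn: identifiers, birth and assessment datetimes (minute
#' resolution, UTC), the mother's last-menstrual-period date when known,
#' weights in grams, foot length in millimetres, temperature with its unit,
#' a 60-second breath count, and tri-state (`"yes"`/`"no"`/`"na"`)
#' observations for the eight direct danger signs and the two five-item
#' feeding checklists. `"na"` means *not assessed*, which is distinct from a
#' negative finding; records captured through the guided form engine never
#' contain `"na"` for required items.
#'
#' @param infant_id Opaque identifier string.
#' @param sex `"female"`, `"male"` or `"unrecorded"`.
#' @param birth_datetime,assessment_datetime `POSIXct` (coerced; truncated
#'   to whole minutes, UTC).
#' @param lmp_date Optional `Date`; `NA` when the mother cannot recall it.
#' @param birth_weight_g,current_weight_g Optional weights in grams.
#' @param foot_length_mm Optional foot length in millimetres.
#' @param temperature Optional temperature value, in `temperature_unit`.
#' @param temperature_unit `"C"` or `"F"`.
#' @param breath_count_60s Optional breaths counted over one minute.
#' @param signs Named character vector of tri-states over [sign_names()].
#'   Missing names default to `"na"`.
#' @param feeding_intolerance Named tri-states over
#'   [feeding_intolerance_items()].
#' @param breastfeeding Named tri-states over [breastfeeding_items()]
#'   (`"yes"` is favourable).
#' @return An object of class `infant_case`.
#' @export
infant_case <- function(infant_id,
                        sex = "unrecorded",
                        birth_datetime,
                        assessment_datetime,
                        lmp_date = NA,
                        birth_weight_g = NA_real_,
                        current_weight_g = NA_real_,
                        foot_length_mm = NA_real_,
                        temperature = NA_real_,
                        temperature_unit = "C",
                        breath_count_60s = NA_integer_,
                        signs = character(),
                        feeding_intolerance = character(),
                        breastfeeding = character()) {
  to_min <- function(x) {
    x <- as.POSIXct(x, tz = "UTC")
    as.POSIXct(floor(as.numeric(x) / 60) * 60, origin = "1970-01-01", tz = "UTC")
  }
  fill_tristate <- function(x, nm) {
    out <- stats::setNames(rep("na", length(nm)), nm)
    if (length(x)) {
      x <- stats::setNames(as.character(x), names(x))
      bad <- setdiff(names(x), nm)
      if (length(bad)) stop("unknown tri-state item(s): ", paste(bad, collapse = ", "))
      out[names(x)] <- x
    }
    out
  }
  structure(list(
    infant_id = as.character(infant_id),
    sex = match.arg(sex, c("female", "male", "unrecorded")),
    birth_datetime = to_min(birth_datetime),
    assessment_datetime = to_min(assessment_datetime),
    lmp_date = if (length(lmp_date) == 1 && is.na(lmp_date)) as.Date(NA) else as.Date(lmp_date),
    birth_weight_g = as.numeric(birth_weight_g),
    current_weight_g = as.numeric(current_weight_g),
    foot_length_mm = as.numeric(foot_length_mm),
    temperature = as.numeric(temperature),
    temperature_unit = match.arg(temperature_unit, c("C", "F")),
    breath_count_60s = as.integer(breath_count_60s),
    signs = fill_tristate(signs, sign_names()),
    feeding_intolerance = fill_tristate(feeding_intolerance, feeding_intolerance_items()),
    breastfeeding = fill_tristate(breastfeeding, breastfeeding_items())
  ), class = "infant_case")
}

#' @export
print.infant_case <- function(x, ...) {
  cat("<infant_case>", x$infant_id, "\n")
  cat("  born:", format(x$birth_datetime, "%Y-%m-%d %H:%M"),
      " assessed:", format(x$assessment_datetime, "%Y-%m-%d %H:%M"), "\n")
  cat("  weights (g): birth", x$birth_weight_g, "current", x$current_weight_g,
      " foot (mm):", x$foot_length_mm, "\n")
  cat("  temp:", x$temperature, x$temperature_unit,
      " RR:", x$breath_count_60s, "\n")
  pos <- names(x$signs)[x$signs == "yes"]
  cat("  signs present:", if (length(pos)) paste(pos, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Validate an infant case against the data-entry constraints
#'
#' Checks the ordering and range invariants the guided form enforces at
#' entry time: assessment not before birth, LMP not after birth, weights in
#' (200, 8000] g, normalized temperature in \[25, 45\] degrees C, breath count
#' at most 200, and valid tri-state codes. Violations are collected, not
#' thrown, so a batch loader can report all problems in a file at once.
#'
#' @param case An [infant_case()].
#' @return A list of class `case_validation` with elements `valid` (logical)
#'   and `errors` (data frame with columns `field`, `rule`, `message`).
#' @export
validate_case <- function(case) {
  stopifnot(inherits(case, "infant_case"))
  errs <- list()
  bad <- function(field, rule, message) {
    errs[[length(errs) + 1L]] <<- data.frame(
      field = field, rule = rule, message = message, stringsAsFactors = FALSE)
  }

  if (case$assessment_datetime < case$birth_datetime) {
    bad("assessment_datetime", "ordering", "assessment precedes birth")
  }
  if (!is.na(case$lmp_date) && case$lmp_date > as.Date(case$birth_datetime, tz = "UTC")) {
    bad("lmp_date", "ordering", "LMP after birth date")
  }
  for (w in c("birth_weight_g", "current_weight_g")) {
    v <- case[[w]]
    if (!is.na(v) && (v <= 200 || v > 8000)) {
      bad(w, "range", sprintf("weight %g g outside (200, 8000]", v))
    }
  }
  if (!is.na(case$foot_length_mm) &&
      (case$foot_length_mm < 30 || case$foot_length_mm > 120)) {
    bad("foot_length_mm", "range",
        sprintf("foot length %g mm outside [30, 120]", case$foot_length_mm))
  }
  if (!is.na(case$temperature)) {
    tc <- normalize_temperature(case$temperature, case$temperature_unit)
    if (tc < 25 || tc > 45) {
      bad("temperature", "range", sprintf("temperature %g degC outside [25, 45]", tc))
    }
  }
  if (!is.na(case$breath_count_60s) &&
      (case$breath_count_60s < 0 || case$breath_count_60s > 200)) {
    bad("breath_count_60s", "range", "breath count outside [0, 200]")
  }
  for (grp in c("signs", "feeding_intolerance", "breastfeeding")) {
    v <- case[[grp]]
    off <- v[!v %in% TRISTATE_OBS]
    if (length(off)) {
      bad(grp, "code", paste("invalid tri-state code for", paste(names(off), collapse = ", ")))
    }
  }

  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(field = character(), rule = character(), message = character())
  structure(list(valid = nrow(errors) == 0L, errors = errors, case = case),
            class = "case_validation")
}

#' @export
print.case_validation <- function(x, ...) {
  if (x$valid) cat("valid infant_case\n") else {
    cat("invalid infant_case:", nrow(x$errors), "violation(s)\n")
    print(x$errors, row.names = FALSE)
  }
  invisible(x)
}

#' Postnatal age in whole calendar days
#'
#' Floor of the elapsed time between birth and assessment, in days; a
#' 6.9-day interval is age 6. Newborn care eligibility requires age
#' strictly under 28 days.
#'
#' @param birth,assessment `POSIXct` datetimes.
#' @return Integer days.
#' @export
postnatal_age_days <- function(birth, assessment) {
  birth <- as.POSIXct(birth, tz = "UTC")
  assessment <- as.POSIXct(assessment, tz = "UTC")
  if (assessment < birth) stop("assessment precedes birth", call. = FALSE)
  as.integer(floor(as.numeric(difftime(assessment, birth, units = "days"))))
}

#' Gestational age at birth from the LMP date
#'
#' Exact `(birth - lmp) / 7` weeks; the one-decimal form is for display
#' only. The preterm cut-off is a strict `< 37.0` weeks.
#'
#' @param lmp,birth `Date`s (coerced).
#' @return Numeric weeks (exact).
#' @export
gestational_age_weeks <- function(lmp, birth) {
  lmp <- as.Date(lmp); birth <- as.Date(birth)
  if (lmp > birth) stop("LMP after birth date", call. = FALSE)
  as.numeric(birth - lmp) / 7
}

#' Percent weight change since birth
#'
#' `100 * (current - birth) / birth`; negative values are loss. Both
#' weights must be positive.
#'
#' @param birth_weight_g,current_weight_g Weights in grams.
#' @return Numeric percent (exact; round for display).
#' @export
weight_change_percent <- function(birth_weight_g, current_weight_g) {
  if (birth_weight_g <= 0 || current_weight_g <= 0) {
    stop("weights must be positive", call. = FALSE)
  }
  100 * (current_weight_g - birth_weight_g) / birth_weight_g
}

#' Normalize a temperature reading to degrees Celsius
#'
#' Fahrenheit readings are converted via `(F - 32) * 5/9`; results are
#' stored to one decimal, the resolution all threshold comparisons use.
#'
#' @param value Temperature reading.
#' @param unit `"C"` or `"F"`.
#' @return Celsius value rounded to 0.1.
#' @export
normalize_temperature <- function(value, unit = c("C", "F")) {
  unit <- match.arg(unit)
  stopifnot_scalar_number(value, "temperature")
  c_val <- if (unit == "F") (value - 32) * 5 / 9 else value
  round_half_up(c_val, 1)
}

#' Derived measures the decision-support app auto-calculates
#'
#' Computes postnatal age (and the under-28-days eligibility flag),
#' gestational age from LMP when recorded, percent weight change when both
#' weights are present, the respiratory rate (the 60-second count verbatim),
#' and the normalized Celsius temperature.
#'
#' @param case A validated [infant_case()].
#' @return A list of class `derived_measures` with elements
#'   `postnatal_age_days`, `eligible`, `gestational_age_weeks`, `preterm`,
#'   `weight_change_percent`, `respiratory_rate_bpm`, `temperature_C`
#'   (absent inputs yield `NA`).
#' @export
derive_measures <- function(case) {
  stopifnot(inherits(case, "infant_case"))
  age <- postnatal_age_days(case$birth_datetime, case$assessment_datetime)
  ga <- if (!is.na(case$lmp_date)) {
    gestational_age_weeks(case$lmp_date, as.Date(case$birth_datetime, tz = "UTC"))
  } else NA_real_
  wc <- if (!is.na(case$birth_weight_g) && !is.na(case$current_weight_g)) {
    weight_change_percent(case$birth_weight_g, case$current_weight_g)
  } else NA_real_
  tc <- if (!is.na(case$temperature)) {
    normalize_temperature(case$temperature, case$temperature_unit)
  } else NA_real_
  structure(list(
    postnatal_age_days = age,
    eligible = age < 28,
    gestational_age_weeks = ga,
    preterm = if (is.na(ga)) NA else ga < 37,
    weight_change_percent = wc,
    respiratory_rate_bpm = if (is.na(case$breath_count_60s)) NA_integer_ else case$breath_count_60s,
    temperature_C = tc
  ), class = "derived_measures")
}
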