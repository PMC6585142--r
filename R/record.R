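#' One assessor's encounter record
#'
#' Holds what a community health worker actually captured for one infant
#' with one method: the answers (item id to value; `NA` marks an item that
#' was reached but not recorded -- only paper records may contain these),
#' the written or generated care recommendations, and the start/end times.
#' Mobile records are produced through [run_form()], which cannot leave a
#' required item unanswered; paper records are ingested as-is. This
#' asymmetry is the mechanism under study and is checked structurally when
#' a `schema` is supplied.
#'
#' @param method `"mobile"` or `"paper"`.
#' @param chw_id,infant_id Identifier strings.
#' @param answers Named list of answers.
#' @param recommendations Character vector of care recommendations.
#' @param start_time,end_time `POSIXct`; `end_time` must not precede
#'   `start_time`.
#' @param study_day Optional integer; day-1 records are excluded from the
#'   full-assessment denominator (the form gained explicit yes/no response
#'   choices after the first day).
#' @param schema Optional [form_schema()]; when given and
#'   `method == "mobile"`, required non-skipped items must all be resolved.
#' @return A list of class `assessment_record`.
#' @export
assessment_record <- function(method = c("mobile", "paper"),
                              chw_id, infant_id,
                              answers = list(),
                              recommendations = character(),
                              start_time = as.POSIXct("2017-03-15 08:00", tz = "UTC"),
                              end_time = start_time,
                              study_day = NA_integer_,
                              schema = NULL) {
  method <- match.arg(method)
  start_time <- as.POSIXct(start_time, tz = "UTC")
  end_time <- as.POSIXct(end_time, tz = "UTC")
  if (end_time < start_time) stop("end_time precedes start_time", call. = FALSE)
  if (method == "mobile" && !is.null(schema)) {
    for (item in schema$items) {
      if (!item$required || !is.null(item$compute)) next
      if (item_skipped(schema, item, answers)) next
      v <- answers[[item$id]]
      if (is.null(v) || (length(v) == 1L && is.na(v))) {
        stop("mobile record leaves required item '", item$id, "' unrecorded",
             call. = FALSE)
      }
    }
  }
  structure(list(
    method = method, chw_id = as.character(chw_id),
    infant_id = as.character(infant_id),
    answers = answers, recommendations = recommendations,
    start_time = start_time, end_time = end_time,
    study_day = study_day
  ), class = "assessment_record")
}

answer_recorded <- function(answers, id) {
  v <- answers[[id]]
  !is.null(v) && !(length(v) == 1L && is.na(v))
}

#' Audit one record for completeness
#'
#' Computes the completeness flags the study tabulates: respiratory rate,
#' temperature and weight (birth *or* current) recorded; at least one care
#' recommendation given; the weight-loss and postnatal-age calculations
#' present; gestational age calculated, evaluated only when an LMP was
#' recorded (`NA` otherwise, so such records drop out of that denominator);
#' and *full assessment*, which requires every danger-sign item resolved
#' yes/no plus the recorded vitals, weight and a recommendation.
#'
#' @param record An [assessment_record()].
#' @param lmp_recorded Override for whether an LMP was captured; defaults
#'   to presence of the `lmp_date` answer.
#' @return A list of class `completeness_flags`.
#' @export
completeness_report <- function(record, lmp_recorded = NULL) {
  a <- record$answers
  if (is.null(lmp_recorded)) lmp_recorded <- answer_recorded(a, "lmp_date")
  rr <- answer_recorded(a, "breath_count_60s")
  temp <- answer_recorded(a, "temperature_c")
  weight <- answer_recorded(a, "birth_weight_g") || answer_recorded(a, "current_weight_g")
  any_rec <- length(record$recommendations) > 0L
  signs_resolved <- all(vapply(paste0("sign_", sign_names()), function(id) {
    answer_recorded(a, id) && a[[id]] %in% c("yes", "no")
  }, logical(1)))
  structure(list(
    full_assessment = signs_resolved && rr && temp && weight && any_rec,
    any_recommendation = any_rec,
    rr_recorded = rr,
    temp_recorded = temp,
    weight_recorded = weight,
    weight_loss_calculated = answer_recorded(a, "weight_change_pct"),
    ga_calculated_if_lmp = if (lmp_recorded) answer_recorded(a, "ga_weeks") else NA,
    postnatal_age_calculated = answer_recorded(a, "postnatal_age_days")
  ), class = "completeness_flags")
}

#' Audit a batch of records
#'
#' @param records List of [assessment_record()].
#' @return Data frame with one row per record: `method`, `chw_id`,
#'   `infant_id`, `study_day` and the completeness flags.
#' @export
audit_records <- function(records) {
  rows <- lapply(records, function(r) {
    fl <- completeness_report(r)
    cbind(data.frame(method = r$method, chw_id = r$chw_id,
                     infant_id = r$infant_id, study_day = r$study_day,
                     stringsAsFactors = FALSE),
          as.data.frame(unclass(fl)))
  })
  do.call(rbind, rows)
}

#' Render the findings summary page
#'
#' A deterministic plain-text rendering of the app's summary page: the
#' positive danger signs and conditions, unassessable items, the feeding
#' advice, referral status and counseling items, and the follow-up date.
#' Empty sections are elided.
#'
#' @param case The [infant_case()].
#' @param profile Its [classify_case()] profile.
#' @param plan Its [build_plan()] management plan.
#' @return A single character string.
#' @export
summary_report <- function(case, profile, plan) {
  lab <- function(x) gsub("_", " ", x)
  pos <- names(profile$conditions)[profile$conditions == "positive"]
  na_ <- names(profile$conditions)[profile$conditions == "na"]
  lines <- c(
    sprintf("ASSESSMENT SUMMARY - infant %s", case$infant_id),
    sprintf("Postnatal age: %d days%s", profile$derived$postnatal_age_days,
            if (!profile$eligible) " (outside newborn period)" else ""),
    if (!is.na(profile$derived$gestational_age_weeks)) {
      sprintf("Gestational age: %.1f weeks%s",
              round_half_up(profile$derived$gestational_age_weeks, 1),
              if (identical(profile$preterm, "positive")) " (PRETERM)" else "")
    },
    if (length(pos)) c("Danger signs and conditions identified:",
                       paste0("  - ", lab(pos)))
    else "No danger signs identified.",
    if (length(na_)) c("Not assessable:", paste0("  - ", lab(na_))),
    if (plan$refer) c("REFER to facility. Reasons:",
                      paste0("  - ", lab(plan$referral_reasons))),
    if (length(plan$counseling)) c("Counseling for the mother:",
                                   paste0("  - ", lab(plan$counseling))),
    if (!is.na(plan$follow_up_date)) sprintf("Follow-up visit: %s", format(plan$follow_up_date))
  )
  paste(unlist(lines), collapse = "\n")
}

#' Flatten records to a data frame
#'
#' One row per record with scalar answers as columns (list answers are
#' dropped), for CSV export.
#'
#' @param records List of [assessment_record()].
#' @return Data frame.
#' @export
records_to_df <- function(records) {
  ids <- sort(unique(unlist(lapply(records, function(r) names(r$answers)))))
  rows <- lapply(records, function(r) {
    row <- data.frame(method = r$method, chw_id = r$chw_id,
                      infant_id = r$infant_id, study_day = r$study_day,
                      start_time = format(r$start_time, "%Y-%m-%dT%H:%M"),
                      end_time = format(r$end_time, "%Y-%m-%dT%H:%M"),
                      n_recommendations = length(r$recommendations),
                      stringsAsFactors = FALSE)
    for (id in ids) {
      v <- r$answers[[id]]
      row[[id]] <- if (is.null(v) || length(v) != 1L) NA_character_ else as.character(v)
    }
    row
  })
  do.call(rbind, rows)
}
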