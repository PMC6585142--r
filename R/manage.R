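#' Decide referral from a condition profile
#'
#' Referral is recommended on the presence of any single danger sign; small
#' infants additionally refer on the configured lower-threshold additions
#' (by default moderate weight loss or breastfeeding problems). The reasons
#' list every firing condition.
#'
#' @param profile A `condition_profile` from [classify_case()].
#' @param config A [management_config()].
#' @return List with `refer` (logical) and `referral_reasons` (character).
#' @export
decide_referral <- function(profile, config = management_config()) {
  conds <- profile$conditions
  missing_rules <- setdiff(config$referral_conditions, names(conds))
  if (length(missing_rules)) {
    stop("referral rule references unknown condition(s): ",
         paste(missing_rules, collapse = ", "), call. = FALSE)
  }
  reasons <- config$referral_conditions[conds[config$referral_conditions] == "positive"]
  if (conds[["small"]] == "positive") {
    adds <- config$small_referral_additions[conds[config$small_referral_additions] == "positive"]
    reasons <- union(reasons, adds)
  }
  reasons <- intersect(names(conds), reasons)  # canonical order
  list(refer = length(reasons) > 0L, referral_reasons = reasons)
}

# predicates the default counseling rule table can reference
counseling_predicates <- function(conds) {
  pos <- function(nm) conds[[nm]] == "positive"
  list(
    small_or_hypothermia = pos("small") || pos("hypothermia"),
    small_and_breastfeeding_problems = pos("small") && pos("breastfeeding_problems"),
    weight_loss_or_poor_feeding =
      pos("moderate_weight_loss") || pos("severe_weight_loss") || pos("poor_feeding"),
    breastfeeding_problems = pos("breastfeeding_problems"),
    umbilicus_red_or_pus = pos("umbilicus_red_or_pus"),
    small = pos("small"),
    hypothermia = pos("hypothermia")
  )
}

#' Select counseling items for a profile
#'
#' Takes the union of the items of every counseling rule whose predicate
#' fires on the profile. See [management_config()] for the default mapping
#' (kangaroo mother care and thermal care for small or hypothermic infants,
#' cup feeding and small-infant breastfeeding advice, increased feeding
#' frequency on weight loss or poor feeding, general breastfeeding support,
#' cord-care advice).
#'
#' @inheritParams decide_referral
#' @return Character vector (subset of [counseling_item_names()]).
#' @export
counseling_items <- function(profile, config = management_config()) {
  preds <- counseling_predicates(profile$conditions)
  items <- character()
  for (rule in config$counseling_rules) {
    p <- preds[[rule$when]]
    if (is.null(p)) stop("unknown counseling predicate: ", rule$when, call. = FALSE)
    if (isTRUE(p)) items <- union(items, rule$items)
  }
  intersect(counseling_item_names(), items)  # canonical order
}

#' Schedule the follow-up visit
#'
#' Referred infants get no scheduled follow-up (referral supersedes it).
#' Small infants and infants with any moderate finding are seen again after
#' 2 days by default; all others after 7.
#'
#' @inheritParams decide_referral
#' @param assessment_date `Date` of the assessment.
#' @param refer Referral decision already made for this profile.
#' @return A `Date`, or `NA` when referred.
#' @export
follow_up_date <- function(profile, assessment_date, refer,
                           config = management_config()) {
  if (refer) return(as.Date(NA))
  assessment_date <- as.Date(assessment_date)
  soon <- profile$conditions[["small"]] == "positive" ||
    profile$conditions[["moderate_weight_loss"]] == "positive"
  assessment_date + if (soon) config$follow_up_small_days else config$follow_up_default_days
}

#' Build the full management plan
#'
#' Composes referral decision, counseling selection and follow-up
#' scheduling into the summary-page output: a deterministic function of the
#' profile and the rule tables.
#'
#' @inheritParams follow_up_date
#' @return A list of class `management_plan` with `refer`,
#'   `referral_reasons`, `counseling` and `follow_up_date`.
#' @export
build_plan <- function(profile, assessment_date, config = management_config()) {
  ref <- decide_referral(profile, config)
  structure(list(
    infant_id = profile$infant_id,
    refer = ref$refer,
    referral_reasons = ref$referral_reasons,
    counseling = counseling_items(profile, config),
    follow_up_date = follow_up_date(profile, assessment_date, ref$refer, config)
  ), class = "management_plan")
}

#' @export
print.management_plan <- function(x, ...) {
  cat("<management_plan>", x$infant_id, "\n")
  cat("  refer:", x$refer, "\n")
  if (x$refer) cat("  reasons:", paste(x$referral_reasons, collapse = ", "), "\n")
  cat("  counseling:", if (length(x$counseling)) paste(x$counseling, collapse = ", ") else "none", "\n")
  cat("  follow-up:", if (is.na(x$follow_up_date)) "none (referred)" else format(x$follow_up_date), "\n")
  invisible(x)
}

#' Tabulate management plans
#'
#' One row per plan: `refer`, one 0/1 column per counseling item, and
#' `follow_up_date`.
#'
#' @param plans List of `management_plan`.
#' @return Data frame.
#' @export
plans_to_df <- function(plans) {
  rows <- lapply(plans, function(p) {
    row <- data.frame(infant_id = p$infant_id, refer = as.integer(p$refer),
                      referral_reasons = paste(p$referral_reasons, collapse = ";"),
                      stringsAsFactors = FALSE)
    for (it in counseling_item_names()) row[[it]] <- as.integer(it %in% p$counseling)
    row$follow_up_date <- if (is.na(p$follow_up_date)) NA_character_ else format(p$follow_up_date)
    row
  })
  do.call(rbind, rows)
}
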