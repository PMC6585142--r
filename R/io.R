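#' Read and write case files
#'
#' Case files hold one assessment encounter per row (CSV) or per object
#' (JSON). Datetimes are ISO-8601 (`YYYY-MM-DDTHH:MM`, UTC), dates
#' `YYYY-MM-DD`, and tri-state observations are coded `yes` / `no` / `na`.
#' Sign columns are prefixed `sign_`, feeding-intolerance items `fi_` and
#' breastfeeding items `bf_`.
#'
#' @param cases A list of [infant_case()] objects.
#' @return `cases_to_df()` returns a data frame with one row per case;
#'   `df_to_cases()` and `read_cases()` return a list of `infant_case`.
#' @export
cases_to_df <- function(cases) {
  rows <- lapply(cases, function(cs) {
    row <- data.frame(
      infant_id = cs$infant_id,
      sex = cs$sex,
      birth_datetime = format(cs$birth_datetime, "%Y-%m-%dT%H:%M", tz = "UTC"),
      assessment_datetime = format(cs$assessment_datetime, "%Y-%m-%dT%H:%M", tz = "UTC"),
      lmp_date = if (is.na(cs$lmp_date)) NA_character_ else format(cs$lmp_date),
      birth_weight_g = cs$birth_weight_g,
      current_weight_g = cs$current_weight_g,
      foot_length_mm = cs$foot_length_mm,
      temperature = cs$temperature,
      temperature_unit = cs$temperature_unit,
      breath_count_60s = cs$breath_count_60s,
      stringsAsFactors = FALSE
    )
    for (nm in sign_names()) row[[paste0("sign_", nm)]] <- cs$signs[[nm]]
    for (nm in feeding_intolerance_items()) row[[paste0("fi_", nm)]] <- cs$feeding_intolerance[[nm]]
    for (nm in breastfeeding_items()) row[[paste0("bf_", nm)]] <- cs$breastfeeding[[nm]]
    row
  })
  do.call(rbind, rows)
}

#' @rdname cases_to_df
#' @param df A data frame in the layout produced by `cases_to_df()`.
#' @export
df_to_cases <- function(df) {
  pick <- function(row, prefix, items) {
    stats::setNames(vapply(items, function(nm) {
      v <- row[[paste0(prefix, nm)]]
      if (is.null(v) || is.na(v)) "na" else as.character(v)
    }, character(1)), items)
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    infant_case(
      infant_id = row$infant_id,
      sex = if (is.na(row$sex)) "unrecorded" else row$sex,
      birth_datetime = as.POSIXct(row$birth_datetime, format = "%Y-%m-%dT%H:%M", tz = "UTC"),
      assessment_datetime = as.POSIXct(row$assessment_datetime, format = "%Y-%m-%dT%H:%M", tz = "UTC"),
      lmp_date = if (is.na(row$lmp_date)) NA else as.Date(row$lmp_date),
      birth_weight_g = row$birth_weight_g,
      current_weight_g = row$current_weight_g,
      foot_length_mm = row$foot_length_mm,
      temperature = row$temperature,
      temperature_unit = if (is.na(row$temperature_unit)) "C" else row$temperature_unit,
      breath_count_60s = row$breath_count_60s,
      signs = pick(row, "sign_", sign_names()),
      feeding_intolerance = pick(row, "fi_", feeding_intolerance_items()),
      breastfeeding = pick(row, "bf_", breastfeeding_items())
    )
  })
}

#' @rdname cases_to_df
#' @param path File path; format from extension (`.csv` or `.json`) unless
#'   given.
#' @param format `"csv"` or `"json"`.
#' @export
write_cases <- function(cases, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.json$", path)) "json" else "csv"
  df <- cases_to_df(cases)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null", auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname cases_to_df
#' @export
read_cases <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.json$", path)) "json" else "csv"
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(infant_id = "character"), na.strings = c("NA", ""))
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  df_to_cases(df)
}

#' Tabulate condition profiles
#'
#' One row per profile, one column per condition with codes
#' `positive` / `negative` / `na`, plus `preterm`, `any_danger_sign` and
#' `eligible`.
#'
#' @param profiles List of `condition_profile` objects from [classify_case()].
#' @return Data frame.
#' @export
profiles_to_df <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    row <- data.frame(infant_id = p$infant_id, stringsAsFactors = FALSE)
    for (nm in condition_names()) row[[nm]] <- p$conditions[[nm]]
    row$preterm <- p$preterm
    row$any_danger_sign <- p$any_danger_sign
    row$eligible <- p$eligible
    row
  })
  do.call(rbind, rows)
}

#' @rdname profiles_to_df
#' @param path Output path (CSV, or JSON by extension).
#' @export
write_profiles <- function(profiles, path) {
  df <- profiles_to_df(profiles)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null", auto_unbox = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}
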