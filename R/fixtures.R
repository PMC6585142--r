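#' Published reference counts from the field validation study
#'
#' The package ships the printed summary counts of the published
#' method-comparison field study (84 paper-form and 86 mobile assessments
#' for the accuracy analysis; 104 and 103 for the completeness audit) as
#' plain CSVs: per-condition correct-classification counts,
#' expert-prevalence and assessor-positive counts, and the completeness
#' counts. These are *inputs* -- the study's published aggregate results --
#' used to reproduce the reported statistics and to calibrate the default
#' assessor-error model.
#'
#' @return A data frame.
#' @export
published_comparison_counts <- function() {
  utils::read.csv(system.file("extdata", "published_comparison_counts.csv",
                              package = "neocds"), stringsAsFactors = FALSE)
}

#' @rdname published_comparison_counts
#' @export
published_prevalence_counts <- function() {
  utils::read.csv(system.file("extdata", "published_prevalence.csv",
                              package = "neocds"), stringsAsFactors = FALSE)
}

#' @rdname published_comparison_counts
#' @export
published_completeness_counts <- function() {
  utils::read.csv(system.file("extdata", "published_completeness_counts.csv",
                              package = "neocds"), stringsAsFactors = FALSE)
}

#' Method-by-correct table for one published condition row
#'
#' @param counts Row source, default [published_comparison_counts()].
#' @param condition Condition name.
#' @return A `concordance_2x2` count vector.
#' @export
published_2x2 <- function(condition, counts = published_comparison_counts()) {
  r <- counts[counts$condition == condition, , drop = FALSE]
  if (nrow(r) != 1L) stop("unknown condition: ", condition, call. = FALSE)
  structure(c(correct_mobile = r$correct_mobile,
              incorrect_mobile = r$n_mobile - r$correct_mobile,
              correct_paper = r$correct_paper,
              incorrect_paper = r$n_paper - r$correct_paper),
            class = "concordance_2x2")
}

#' Synthetic record set reproducing the published completeness counts
#'
#' Builds a deterministic set of assessment records whose completeness
#' audit reproduces a given completeness count table exactly: for each
#' arm, flags are assigned to leading records so every row's numerator and
#' denominator match, with the full-assessment denominator realized by
#' flagging the surplus records as study day 1 (the day before the paper
#' form gained explicit yes/no response choices). The records are
#' synthetic constructions from the published aggregates, not
#' reconstructions of individual study records.
#'
#' @param counts Count table in the layout of
#'   [published_completeness_counts()].
#' @return List of [assessment_record()].
#' @export
completeness_fixture <- function(counts = published_completeness_counts()) {
  need <- function(measure, col) {
    r <- counts[counts$measure == measure, ]
    c(k = r[[paste0("k_", col)]], n = r[[paste0("n_", col)]])
  }
  build_arm <- function(arm) {
    n_total <- need("any_recommendation", arm)["n"]
    n_full_den <- need("full_assessment", arm)["n"]
    k <- list(
      full = need("full_assessment", arm)["k"],
      rec = need("any_recommendation", arm)["k"],
      rr = need("rr_recorded", arm)["k"],
      temp = need("temp_recorded", arm)["k"],
      weight = need("weight_recorded", arm)["k"],
      wl = need("weight_loss_calculated", arm)["k"],
      ga = need("ga_calculated_if_lmp", arm)["k"],
      age = need("postnatal_age_calculated", arm)["k"]
    )
    n_lmp <- need("ga_calculated_if_lmp", arm)["n"]
    if (k$full > min(k$rec, k$rr, k$temp, k$weight)) {
      stop("inconsistent counts: full assessments exceed a component count",
           call. = FALSE)
    }
    method <- if (arm == "paper") "paper" else "mobile"
    lapply(seq_len(n_total), function(i) {
      ans <- list()
      # guided mobile entry always resolves the sign items; on paper only
      # the fully-assessed records have them all answered
      resolved <- method == "mobile" || i <= k$full
      for (nm in sign_names()) ans[[paste0("sign_", nm)]] <- if (resolved) "no" else NA
      ans$breath_count_60s <- if (i <= k$rr) 45 else NA
      ans$temperature_c <- if (i <= k$temp) 37.0 else NA
      # one mobile record has no weight available; keep it out of the
      # full-assessment denominator by placing missing-weight records last
      ans$birth_weight_g <- if (i <= k$weight) 3000 else NA
      ans$current_weight_g <- if (i <= k$weight) 2940 else NA
      ans$weight_change_pct <- if (i <= k$wl) -2.0 else NA
      ans$postnatal_age_days <- if (i <= k$age) 5 else NA
      ans$lmp_date <- if (i <= n_lmp) "2016-06-10" else NA
      ans$ga_weeks <- if (i <= k$ga) 40.0 else NA
      assessment_record(
        method = method, chw_id = sprintf("chw%02d", (i %% 12) + 1),
        infant_id = sprintf("%s-%03d", arm, i),
        answers = ans,
        recommendations = if (i <= k$rec) "follow-up visit scheduled" else character(),
        study_day = if (i > n_full_den) 1L else 2L
      )
    })
  }
  c(build_arm("paper"), build_arm("mobile"))
}
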