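#' Per-condition correctness against the gold standard
#'
#' A call is correct when it is resolved (positive or negative) and equal
#' to the gold-standard call; an unassessable (`na`) call can never be
#' correct -- a missed assessment is counted against the assessor.
#'
#' @param assessor,gold `condition_profile` objects over the same
#'   condition set.
#' @return Named logical vector over [condition_names()].
#' @export
correctness <- function(assessor, gold) {
  a <- assessor$conditions; g <- gold$conditions
  if (!identical(sort(names(a)), sort(names(g)))) {
    stop("condition sets differ between assessor and gold profiles", call. = FALSE)
  }
  g <- g[names(a)]
  stats::setNames(a != "na" & a == g, names(a))
}

#' Collapse labeled assessments to a method-by-correct 2x2 table
#'
#' @param labeled Data frame of labeled assessments with columns `method`,
#'   `condition`, `correct`.
#' @param condition Condition to tabulate.
#' @return Named integer vector `(correct_mobile, incorrect_mobile,
#'   correct_paper, incorrect_paper)` of class `concordance_2x2`.
#' @export
condition_2x2 <- function(labeled, condition) {
  d <- labeled[labeled$condition == condition, , drop = FALSE]
  n_m <- sum(d$method == "mobile"); n_p <- sum(d$method == "paper")
  if (n_m == 0L || n_p == 0L) {
    stop("degenerate table: no records for one of the methods (", condition, ")",
         call. = FALSE)
  }
  cm <- sum(d$correct[d$method == "mobile"])
  cp <- sum(d$correct[d$method == "paper"])
  structure(c(correct_mobile = cm, incorrect_mobile = n_m - cm,
              correct_paper = cp, incorrect_paper = n_p - cp),
            class = "concordance_2x2")
}

as_2x2 <- function(table) {
  if (inherits(table, "concordance_2x2") || (is.numeric(table) && length(table) == 4L)) {
    matrix(as.numeric(table), nrow = 2, byrow = TRUE,
           dimnames = list(method = c("mobile", "paper"),
                           result = c("correct", "incorrect")))
  } else if (is.matrix(table) && all(dim(table) == 2L)) {
    table
  } else stop("expected a 2x2 table or length-4 count vector", call. = FALSE)
}

#' Compare correct-classification proportions between methods
#'
#' Proportions per arm, their difference in percentage points, and a
#' Pearson chi-squared test of independence on the 2x2 table (1 df, no
#' continuity correction). With a zero margin the test is undefined and
#' reported as `NA`.
#'
#' @param table A [condition_2x2()] result (or any
#'   `(correct_mobile, incorrect_mobile, correct_paper, incorrect_paper)`
#'   counts).
#' @return List: `prop_mobile`, `prop_paper`, `ppd` (percentage points,
#'   mobile minus paper), `chi2_stat`, `chi2_p`.
#' @export
compare_proportions <- function(table) {
  m <- as_2x2(table)
  if (any(rowSums(m) == 0)) stop("empty method arm", call. = FALSE)
  pm <- m[1, 1] / sum(m[1, ]); pp <- m[2, 1] / sum(m[2, ])
  if (any(colSums(m) == 0)) {
    chi2 <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    chi2 <- unname(ct$statistic); p <- ct$p.value
  }
  list(prop_mobile = pm, prop_paper = pp, ppd = 100 * (pm - pp),
       chi2_stat = chi2, chi2_p = p)
}

#' Crude odds ratio of correct classification, mobile vs paper
#'
#' The cross-product ratio of the collapsed 2x2 with a log-scale Wald 95%
#' confidence interval. When a zero cell occurs the Haldane-Anscombe
#' correction (0.5 added to every cell) is applied and the estimate is
#' flagged as corrected.
#'
#' @inheritParams compare_proportions
#' @param conf_level Confidence level for the Wald interval.
#' @return List: `or_point`, `ci` (low, high), `p` (Wald test of log-OR =
#'   0), `corrected` (logical).
#' @export
crude_odds_ratio <- function(table, conf_level = 0.95) {
  m <- as_2x2(table)
  corrected <- any(m == 0)
  if (corrected) m <- m + 0.5
  or_ <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  se <- sqrt(sum(1 / m))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or_) + c(-1, 1) * z * se)
  p <- 2 * stats::pnorm(-abs(log(or_) / se))
  list(or_point = or_, ci = ci, p = p, corrected = corrected)
}

#' Cluster-robust odds ratio (population-averaged logit)
#'
#' Fits the population-averaged logistic model
#' `correct ~ method` by generalized estimating equations with a binomial
#' family, logit link and *independence* working correlation -- i.e. an
#' ordinary logistic GLM score equation -- and replaces the model-based
#' variance with the cluster-robust (sandwich) estimate over assessor
#' clusters. With independence working correlation the point estimate is
#' exactly the crude odds ratio of the collapsed table for any cluster
#' assignment; clustering affects only the interval and p-value.
#'
#' @param labeled Data frame with logical `correct`, `method`
#'   (`"mobile"`/`"paper"`) and cluster column.
#' @param cluster Name of the cluster id column (default `"chw_id"`).
#' @param conf_level Confidence level.
#' @return List: `or_point`, `ci`, `p`, `n_clusters`.
#' @export
cluster_robust_or <- function(labeled, cluster = "chw_id", conf_level = 0.95) {
  d <- labeled
  d$.y <- as.logical(d$correct)
  d$.mobile <- as.integer(d$method == "mobile")
  cl <- d[[cluster]]
  n_cl <- length(unique(cl))
  if (n_cl < 2L) {
    warning("fewer than 2 clusters: robust variance is unreliable")
  }
  fit <- stats::glm(.y ~ .mobile, family = stats::binomial(), data = d)
  vc <- sandwich::vcovCL(fit, cluster = cl)
  b <- stats::coef(fit)[".mobile"]
  se <- sqrt(vc[".mobile", ".mobile"])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or_point = unname(exp(b)),
       ci = unname(exp(b + c(-1, 1) * z * se)),
       p = unname(2 * stats::pnorm(-abs(b / se))),
       n_clusters = n_cl)
}

#' Compare mean completion times between methods
#'
#' Two-sided two-sample t-test (Welch by default) on per-assessment
#' completion times in minutes.
#'
#' @param times_mobile,times_paper Numeric vectors (>= 2 values each).
#' @param var_equal Pool the variances instead of Welch.
#' @return List: `mean_mobile`, `mean_paper`, `diff` (mobile minus paper),
#'   `ci95`, `p`.
#' @export
mean_time_comparison <- function(times_mobile, times_paper, var_equal = FALSE) {
  if (length(times_mobile) < 2L || length(times_paper) < 2L) {
    stop("need at least two observations per arm", call. = FALSE)
  }
  tt <- stats::t.test(times_mobile, times_paper, var.equal = var_equal)
  list(mean_mobile = mean(times_mobile), mean_paper = mean(times_paper),
       diff = mean(times_mobile) - mean(times_paper),
       ci95 = unname(tt$conf.int), p = tt$p.value, statistic = unname(tt$statistic))
}

#' Build labeled assessments from assessor and gold profiles
#'
#' Expands each (assessor profile, gold profile) pair into one row per
#' condition with the assessor call, gold call and correctness.
#'
#' @param assessments Data frame with columns `chw_id`, `infant_id`,
#'   `method` and a list-column `profile` of `condition_profile`s -- or a
#'   list of such profiles passed via `profiles` with the metadata columns.
#' @param profiles List of assessor `condition_profile`s (one per row of
#'   `assessments` when `assessments` lacks a `profile` column).
#' @param gold Named list of gold `condition_profile`s, indexed by
#'   `infant_id`.
#' @return Data frame of labeled assessments.
#' @export
label_assessments <- function(assessments, profiles = NULL, gold) {
  if (is.null(profiles)) profiles <- assessments$profile
  rows <- lapply(seq_len(nrow(assessments)), function(i) {
    pr <- profiles[[i]]
    g <- gold[[assessments$infant_id[i]]]
    corr <- correctness(pr, g)
    data.frame(
      chw_id = assessments$chw_id[i], infant_id = assessments$infant_id[i],
      method = assessments$method[i], condition = names(corr),
      assessor_call = unname(pr$conditions[names(corr)]),
      gold_call = unname(g$conditions[names(corr)]) == "positive",
      correct = unname(corr), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full study report: completeness and per-condition comparison tables
#'
#' Produces the two tables a method-comparison study prints: (1) the
#' completeness audit (eight rows: full assessment, any recommendation,
#' respiratory rate / temperature / weight recorded, weight-loss,
#' gestational-age and postnatal-age calculations) with per-arm counts,
#' percentage-point differences and chi-squared p-values; day-1 records
#' are excluded from the full-assessment row; and (2) the per-condition
#' correct-classification comparison with proportions, percentage-point
#' difference, chi-squared test and cluster-robust odds ratio.
#'
#' @param records List of [assessment_record()].
#' @param labeled Labeled assessments (see [label_assessments()]).
#' @param conditions Conditions to tabulate (default all 18).
#' @return List of class `study_report` with data frames `completeness`
#'   and `comparison`.
#' @export
study_report <- function(records, labeled, conditions = condition_names()) {
  aud <- audit_records(records)
  not_day1 <- is.na(aud$study_day) | aud$study_day != 1L

  comp_row <- function(flag, label, keep = rep(TRUE, nrow(aud))) {
    res <- list(measure = label)
    counts <- list()
    for (m in c("paper", "mobile")) {
      sel <- aud$method == m & keep & !is.na(aud[[flag]])
      counts[[m]] <- c(k = sum(aud[[flag]][sel]), n = sum(sel))
    }
    kp <- counts$paper; km <- counts$mobile
    pp_ <- if (kp["n"] > 0) kp["k"] / kp["n"] else NA
    pm_ <- if (km["n"] > 0) km["k"] / km["n"] else NA
    tab <- c(km["k"], km["n"] - km["k"], kp["k"], kp["n"] - kp["k"])
    chi_p <- if (all(c(km["n"], kp["n"]) > 0)) {
      cp <- try(compare_proportions(tab), silent = TRUE)
      if (inherits(cp, "try-error")) NA_real_ else cp$chi2_p
    } else NA_real_
    data.frame(measure = label,
               k_paper = unname(kp["k"]), n_paper = unname(kp["n"]),
               pct_paper = unname(100 * pp_),
               k_mobile = unname(km["k"]), n_mobile = unname(km["n"]),
               pct_mobile = unname(100 * pm_),
               ppd = unname(100 * (pm_ - pp_)), chi2_p = chi_p,
               stringsAsFactors = FALSE)
  }

  completeness <- rbind(
    comp_row("full_assessment", "full_assessment", keep = not_day1),
    comp_row("any_recommendation", "any_recommendation"),
    comp_row("rr_recorded", "rr_recorded"),
    comp_row("temp_recorded", "temp_recorded"),
    comp_row("weight_recorded", "weight_recorded"),
    comp_row("weight_loss_calculated", "weight_loss_calculated"),
    comp_row("ga_calculated_if_lmp", "ga_calculated_if_lmp"),
    comp_row("postnatal_age_calculated", "postnatal_age_calculated")
  )

  comparison <- do.call(rbind, lapply(conditions, function(cond) {
    tab <- condition_2x2(labeled, cond)
    pr <- compare_proportions(tab)
    or_cl <- cluster_robust_or(labeled[labeled$condition == cond, , drop = FALSE])
    or_cr <- crude_odds_ratio(tab)
    data.frame(
      condition = cond,
      correct_paper = unname(tab["correct_paper"]),
      n_paper = unname(tab["correct_paper"] + tab["incorrect_paper"]),
      prop_paper = pr$prop_paper,
      correct_mobile = unname(tab["correct_mobile"]),
      n_mobile = unname(tab["correct_mobile"] + tab["incorrect_mobile"]),
      prop_mobile = pr$prop_mobile,
      ppd = pr$ppd, chi2_stat = pr$chi2_stat, chi2_p = pr$chi2_p,
      or_point = or_cl$or_point, or_low = or_cl$ci[1], or_high = or_cl$ci[2],
      or_p = or_cl$p, or_zero_cell = or_cr$corrected,
      stringsAsFactors = FALSE
    )
  }))

  structure(list(completeness = completeness, comparison = comparison),
            class = "study_report")
}

#' Render a study report as text
#'
#' One-decimal half-up rounding, matching the usual printed table style.
#'
#' @param report A [study_report()].
#' @return Character vector of lines.
#' @export
render_report <- function(report) {
  f1 <- function(x) ifelse(is.na(x), "-", sprintf("%.1f", round_half_up(x, 1)))
  fp <- function(p) ifelse(is.na(p), "-", ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
  lines <- c("COMPLETENESS OF ASSESSMENTS (paper vs mobile)")
  for (i in seq_len(nrow(report$completeness))) {
    r <- report$completeness[i, ]
    lines <- c(lines, sprintf(
      "  %-26s %3d/%-3d (%s%%)  %3d/%-3d (%s%%)  ppd %s  p %s",
      r$measure, r$k_paper, r$n_paper, f1(r$pct_paper),
      r$k_mobile, r$n_mobile, f1(r$pct_mobile), f1(r$ppd), fp(r$chi2_p)))
  }
  lines <- c(lines, "", "CORRECT CLASSIFICATION BY CONDITION (paper vs mobile)")
  for (i in seq_len(nrow(report$comparison))) {
    r <- report$comparison[i, ]
    lines <- c(lines, sprintf(
      "  %-26s %3d/%-3d (%s%%)  %3d/%-3d (%s%%)  ppd %s  OR %s (%s, %s)%s  p %s",
      r$condition, r$correct_paper, r$n_paper, f1(100 * r$prop_paper),
      r$correct_mobile, r$n_mobile, f1(100 * r$prop_mobile), f1(r$ppd),
      f1(r$or_point), f1(r$or_low), f1(r$or_high),
      ifelse(r$or_zero_cell, "*", ""), fp(r$or_p)))
  }
  lines
}
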