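#' Assessor error model
#'
#' Per condition and method, the probability that an assessor's call agrees
#' with the gold label: `sens` applies when the gold label is positive,
#' `spec` when it is negative. A CHW-level random effect on the log-odds of
#' a correct call induces clustering by assessor. Paper-form assessments
#' additionally lose fields to non-recording with the published rates
#' (respiratory rate unrecorded 54.8% of the time, temperature 40.4%,
#' weight 2.9%, individual danger-sign items 10% by default, a written
#' recommendation absent 67.3%, the weight-loss calculation absent 4.8%,
#' the postnatal-age calculation absent 26%, the gestational-age
#' calculation absent 79.3% of LMP-recorded forms); guided mobile entry has
#' structurally zero missingness.
#'
#' Default `sens`/`spec` are calibrated from the bundled published counts
#' via [calibrate_error_model()].
#'
#' @param sens,spec Matrices (condition x method) of agreement
#'   probabilities, or `NULL` for the calibrated defaults.
#' @param chw_sd SD of the CHW random effect on the log-odds scale.
#' @param missingness Named list of paper-arm non-recording probabilities:
#'   `temp`, `rr`, `weight`, `sign`, `recommendation`, `weight_loss_calc`,
#'   `postnatal_age_calc`, `ga_calc_given_lmp`.
#' @param n_chws Number of community health workers.
#' @param block_size Assessments per method block in the crossover.
#' @param assessments_per_infant Assessments drawn per infant.
#' @param seed Seed for the simulation's RNG streams.
#' @return A list of class `error_model`.
#' @export
error_model <- function(sens = NULL, spec = NULL, chw_sd = 0.3,
                        missingness = NULL,
                        n_chws = 12, block_size = 6,
                        assessments_per_infant = 2,
                        seed = 20170302) {
  if (is.null(sens) || is.null(spec)) {
    cal <- calibrate_error_model()
    if (is.null(sens)) sens <- cal$sens
    if (is.null(spec)) spec <- cal$spec
  }
  miss_default <- list(temp = 0.404, rr = 0.548, weight = 0.029, sign = 0.10,
                       recommendation = 0.673, weight_loss_calc = 0.048,
                       postnatal_age_calc = 0.26, ga_calc_given_lmp = 0.793)
  if (!is.null(missingness)) miss_default[names(missingness)] <- missingness
  stopifnot(all(unlist(miss_default) >= 0), all(unlist(miss_default) <= 1),
            all(sens >= 0 & sens <= 1), all(spec >= 0 & spec <= 1))
  structure(list(sens = sens, spec = spec, chw_sd = chw_sd,
                 missingness = miss_default, n_chws = as.integer(n_chws),
                 block_size = as.integer(block_size),
                 assessments_per_infant = as.integer(assessments_per_infant),
                 seed = as.integer(seed)),
            class = "error_model")
}

#' Calibrate sensitivity/specificity from published aggregate counts
#'
#' With prevalence `p`, assessor positive-call rate `q` and correct-call
#' rate `c` (both among resolved assessments), the two moment equations
#' `q = p*sens + (1-p)*(1-spec)` and `c = p*sens + (1-p)*spec` identify
#' `spec = ((c - q)/(1 - p) + 1)/2` and `sens = (c - (1-p)*spec)/p`. For
#' the paper arm, published rates are first rescaled by the arm's
#' field-missingness (an unrecorded field can never be correct) so the
#' returned values describe the assessor's accuracy *when the field is
#' recorded*. Small published cells push some solutions outside \[0, 1\];
#' they are clamped to \[0.02, 0.995\] and zero-prevalence conditions get
#' an arbitrary sensitivity of 0.9 (unidentifiable from the data).
#'
#' @param comparison Correct-classification counts, layout of
#'   [published_comparison_counts()].
#' @param prevalence Prevalence / positive-call counts, layout of
#'   [published_prevalence_counts()].
#' @param missingness Paper-arm missingness list (see [error_model()]).
#' @return List with `sens` and `spec` matrices (condition x
#'   c("mobile", "paper")).
#' @export
calibrate_error_model <- function(comparison = published_comparison_counts(),
                                  prevalence = published_prevalence_counts(),
                                  missingness = list(temp = 0.404, rr = 0.548,
                                                     weight = 0.029, sign = 0.10)) {
  conds <- comparison$condition
  m_paper <- condition_field_missingness(missingness)[conds]
  out_s <- matrix(NA_real_, length(conds), 2, dimnames = list(conds, c("mobile", "paper")))
  out_p <- out_s
  for (i in seq_along(conds)) {
    pr <- prevalence[prevalence$condition == conds[i], ]
    cm <- comparison[i, ]
    for (method in c("mobile", "paper")) {
      sfx <- if (method == "mobile") "mobile" else "paper"
      p <- pr[[paste0("expert_pos_", sfx)]] / pr[[paste0("n_", sfx)]]
      q <- pr[[paste0("chw_pos_", sfx)]] / pr[[paste0("n_", sfx)]]
      cc <- cm[[paste0("correct_", sfx)]] / cm[[paste0("n_", sfx)]]
      m <- if (method == "paper") m_paper[i] else 0
      cc <- min(cc / (1 - m), 0.999)
      q <- min(q / (1 - m), 0.999)
      spec_ <- ((cc - q) / (1 - p) + 1) / 2
      sens_ <- if (p > 0) (cc - (1 - p) * spec_) / p else 0.9
      out_s[i, method] <- min(max(sens_, 0.02), 0.995)
      out_p[i, method] <- min(max(spec_, 0.02), 0.995)
    }
  }
  list(sens = out_s, spec = out_p)
}

#' Per-condition field-missingness of the paper arm
#'
#' Maps field-level non-recording probabilities onto the conditions they
#' make unassessable: temperature drives fever and hypothermia, the breath
#' count drives fast breathing, the weights drive the five size/weight
#' conditions, and the sign probability covers the eight direct signs and
#' the two feeding composites.
#'
#' @param missingness Named list with `temp`, `rr`, `weight`, `sign`.
#' @return Named numeric vector over [condition_names()].
#' @export
condition_field_missingness <- function(missingness) {
  m <- stats::setNames(rep(missingness$sign, length(condition_names())),
                       condition_names())
  m[c("fever", "hypothermia")] <- missingness$temp
  m["fast_breathing"] <- missingness$rr
  m[c("low_birth_weight", "small", "very_low_weight_lt1500",
      "severe_weight_loss", "moderate_weight_loss")] <- missingness$weight
  m
}

#' Expected correct-classification proportion implied by an error model
#'
#' For a condition with prevalence `p`, the expected proportion of correct
#' calls is `(1 - miss) * E_u[plogis(qlogis(base) + u)]` averaged over the
#' gold label (`base` is `sens` on positives, `spec` on negatives) and the
#' CHW random effect `u ~ N(0, chw_sd)` (integrated numerically). This is
#' the target the simulated study's observed proportions are checked
#' against in parameter-recovery runs.
#'
#' @param em An [error_model()].
#' @param prevalence Named prevalence vector over conditions.
#' @param method `"mobile"` or `"paper"`.
#' @return Named numeric vector of expected correct proportions.
#' @export
implied_correct_proportion <- function(em, prevalence,
                                       method = c("mobile", "paper")) {
  method <- match.arg(method)
  conds <- rownames(em$sens)
  miss <- if (method == "paper") condition_field_missingness(em$missingness)[conds]
          else stats::setNames(rep(0, length(conds)), conds)
  avg_logitnorm <- function(base) {
    if (em$chw_sd == 0) return(base)
    f <- function(u) stats::plogis(stats::qlogis(base) + u) * stats::dnorm(u, 0, em$chw_sd)
    stats::integrate(f, -6 * em$chw_sd, 6 * em$chw_sd)$value
  }
  out <- vapply(conds, function(cn) {
    p <- unname(prevalence[cn])
    e_s <- avg_logitnorm(em$sens[cn, method])
    e_p <- avg_logitnorm(em$spec[cn, method])
    (1 - miss[cn]) * (p * e_s + (1 - p) * e_p)
  }, numeric(1))
  stats::setNames(out, conds)
}
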