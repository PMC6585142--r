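test_that("correctness requires a resolved call equal to gold", {
  g <- classify_case(healthy_case(temperature = 39))
  a_same <- g
  expect_true(all(correctness(a_same, g)))

  a <- g; a$conditions["fever"] <- "negative"
  expect_false(correctness(a, g)[["fever"]])

  a <- g; a$conditions["hypothermia"] <- "na"
  expect_false(correctness(a, g)[["hypothermia"]])

  bad <- g; bad$conditions <- bad$conditions[-1]
  expect_error(correctness(bad, g), "condition sets differ")
})

test_that("condition_2x2 counts match a hand tally", {
  # 7 mobile (5 correct), 5 paper (2 correct) for one condition
  labeled <- data.frame(
    method = c(rep("mobile", 7), rep("paper", 5), rep("mobile", 3)),
    condition = c(rep("fever", 12), rep("small", 3)),
    correct = c(rep(TRUE, 5), FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE,
                TRUE, TRUE, TRUE),
    chw_id = "c1", stringsAsFactors = FALSE
  )
  tab <- condition_2x2(labeled, "fever")
  expect_identical(unname(unclass(tab)), c(5L, 2L, 2L, 3L))
  expect_error(condition_2x2(labeled, "small"), "degenerate")
})

test_that("proportion comparison reproduces the published small-infant gap", {
  res <- compare_proportions(c(83, 3, 48, 36))
  expect_equal(round_half_up(res$ppd, 1), 39.4)
  expect_lt(res$chi2_p, 0.001)

  res <- compare_proportions(c(10, 10, 10, 10))
  expect_equal(res$ppd, 0)
  expect_equal(res$chi2_stat, 0)
})

test_that("Pearson statistic matches the textbook formula and the squared z", {
  pearson_oracle <- function(t) {
    m <- matrix(t, 2, byrow = TRUE)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  expect_equal(compare_proportions(c(86, 0, 20, 64))$chi2_stat,
               pearson_oracle(c(86, 0, 20, 64)))

  set.seed(99)
  for (i in 1:50) {
    t <- c(sample(1:60, 2), sample(1:60, 2))
    res <- compare_proportions(t)
    expect_equal(res$chi2_stat, pearson_oracle(t))
    n1 <- t[1] + t[2]; n2 <- t[3] + t[4]
    p1 <- t[1] / n1; p2 <- t[3] / n2; pp <- (t[1] + t[3]) / (n1 + n2)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    expect_equal(res$chi2_stat, z^2)
  }
})

test_that("crude odds ratios reproduce published values and behave symmetrically", {
  expect_equal(round_half_up(crude_odds_ratio(c(83, 3, 48, 36))$or_point, 1), 20.8)
  expect_equal(round_half_up(crude_odds_ratio(c(84, 2, 62, 22))$or_point, 1), 14.9)
  expect_equal(crude_odds_ratio(c(10, 10, 10, 10))$or_point, 1.0)

  set.seed(7)
  for (i in 1:25) {
    t <- c(sample(1:50, 2), sample(1:50, 2))
    a <- crude_odds_ratio(t)
    b <- crude_odds_ratio(t[c(3, 4, 1, 2)])  # swap method labels
    expect_equal(a$or_point, 1 / b$or_point)
    expect_equal(a$ci, sort(1 / b$ci))
  }

  z <- crude_odds_ratio(c(86, 0, 20, 64))
  expect_true(z$corrected)
  expect_true(is.finite(z$or_point))
})

test_that("GEE-independence point estimate equals the crude odds ratio under any clustering", {
  set.seed(123)
  for (i in 1:20) {
    n <- sample(40:120, 1)
    d <- data.frame(
      method = sample(c("mobile", "paper"), n, replace = TRUE, prob = c(0.5, 0.5)),
      chw_id = sample(sprintf("c%02d", 1:6), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    pm <- runif(1, 0.3, 0.95); pp <- runif(1, 0.2, 0.9)
    d$correct <- ifelse(d$method == "mobile", runif(n) < pm, runif(n) < pp)
    # guarantee non-degenerate cells
    if (length(unique(d$method)) < 2 || length(unique(d$correct)) < 2) next
    tab <- c(sum(d$method == "mobile" & d$correct), sum(d$method == "mobile" & !d$correct),
             sum(d$method == "paper" & d$correct), sum(d$method == "paper" & !d$correct))
    if (any(tab == 0)) next
    gee <- cluster_robust_or(d)
    crude <- crude_odds_ratio(tab)
    expect_equal(gee$or_point, crude$or_point, tolerance = 1e-6)
  }
})

test_that("one observation per cluster reduces to ordinary robust logistic", {
  set.seed(5)
  n <- 80
  d <- data.frame(method = rep(c("mobile", "paper"), each = n / 2),
                  chw_id = sprintf("u%03d", 1:n),
                  correct = c(runif(n / 2) < 0.8, runif(n / 2) < 0.5))
  res <- cluster_robust_or(d)
  fit <- stats::glm(correct ~ I(method == "mobile"), binomial(), data = d)
  vc <- sandwich::vcovCL(fit, cluster = seq_len(n))
  se <- sqrt(vc[2, 2])
  expect_equal(log(res$ci[2] / res$or_point) / stats::qnorm(0.975), se,
               tolerance = 1e-6)
})

test_that("completion-time comparison matches a hand-computed Welch t", {
  x <- c(14, 16, 19, 21, 15); y <- c(22, 25, 20, 27)
  res <- mean_time_comparison(x, y)
  sx <- var(x) / length(x); sy <- var(y) / length(y)
  t_hand <- (mean(x) - mean(y)) / sqrt(sx + sy)
  expect_equal(res$statistic, t_hand)

  res <- mean_time_comparison(c(10, 12, 14), c(10, 12, 14))
  expect_equal(res$diff, 0)
  expect_equal(res$p, 1)

  set.seed(31)
  x <- rnorm(103, 17.5, 10.8); y <- rnorm(104, 23.6, 11.6)
  x <- x - mean(x) + 17.5; y <- y - mean(y) + 23.6
  res <- mean_time_comparison(x, y)
  expect_equal(round_half_up(res$diff, 1), -6.1)
})

test_that("study_report produces the two study-shaped tables", {
  co <- generate_cohort(cohort_spec(n_infants = 30, seed = 3))
  sim <- simulate_assessments(co, em = error_model(seed = 4))
  rep <- study_report(sim$records, sim$labeled)
  expect_identical(nrow(rep$completeness), 8L)
  expect_identical(nrow(rep$comparison), 18L)
  expect_true(all(rep$comparison$or_point > 0))
  expect_true(all(rep$completeness$pct_mobile == 100))
  expect_true(all(abs(rep$comparison$ppd -
    100 * (rep$comparison$prop_mobile - rep$comparison$prop_paper)) < 1e-9))
  txt <- render_report(rep)
  expect_true(any(grepl("CORRECT CLASSIFICATION", txt)))
})
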