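make_results <- function(correct_c, n_c, correct_i, n_i,
                         rt = 0.5, mt = 0.15) {
  specs <- tibble::tibble(
    trial_index = seq_len(n_c + n_i),
    phase = "main",
    congruent = rep(c(TRUE, FALSE), c(n_c, n_i))
  )
  results <- tibble::tibble(
    trial_index = specs$trial_index,
    missed = FALSE,
    correct = c(rep(c(TRUE, FALSE), c(correct_c, n_c - correct_c)),
                rep(c(TRUE, FALSE), c(correct_i, n_i - correct_i))),
    reaction_time = rt,
    movement_time = mt
  )
  list(specs = specs, results = results)
}

test_that("subject summaries aggregate by congruence over responded trials", {
  # uniform perfection: both proportions 1, both RT means equal, zero effects
  d <- make_results(30, 30, 30, 30, rt = 0.5)
  s <- summarize_subject(d$results, d$specs, age = 40, subject_id = 7L)
  expect_equal(s$p_correct_congruent, 1)
  expect_equal(s$p_correct_incongruent, 1)
  expect_equal(s$mean_rt_congruent, 0.5)
  expect_equal(s$accuracy_effect, 0)
  expect_equal(s$rt_effect, 0)

  # hand-built 12/30 vs 9/30 table
  d2 <- make_results(12, 30, 9, 30)
  s2 <- summarize_subject(d2$results, d2$specs)
  expect_equal(s2$p_correct_congruent, 0.4)
  expect_equal(s2$p_correct_incongruent, 0.3)
  expect_equal(s2$accuracy_effect, 0.1)

  # RT means use correct trials only: corrupting incorrect-trial RTs is inert
  d3 <- make_results(12, 30, 9, 30, rt = 0.5)
  d3$results$reaction_time[!d3$results$correct] <- 99
  s3 <- summarize_subject(d3$results, d3$specs)
  expect_equal(s3$mean_rt_congruent, 0.5)
  expect_equal(s3$mean_rt_incongruent, 0.5)

  # missed trials leave the accuracy denominator
  d4 <- make_results(12, 30, 9, 30)
  d4$results$missed[d4$results$trial_index %in% 1:5] <- TRUE  # 5 correct out
  d4$results$correct[d4$results$missed] <- NA
  s4 <- summarize_subject(d4$results, d4$specs)
  expect_equal(s4$n_missed, 5)
  expect_equal(s4$p_correct_congruent, 7 / 25)

  # zero correct trials in a condition flags the subject
  d5 <- make_results(0, 30, 9, 30)
  s5 <- summarize_subject(d5$results, d5$specs)
  expect_true(s5$flagged)
  expect_true(is.na(s5$mean_rt_congruent))
})

test_that("paired effect test matches the one-sample t construction", {
  # symmetric effects: mean 0, t 0, p 1
  sym <- paired_effect_test(c(0.2, -0.2))
  expect_equal(sym$estimate, 0)
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p.value, 1)

  # agreement with the closed form on a fixed vector
  x <- c(0.12, 0.03, 0.21, 0.08, -0.02, 0.15)
  pt <- paired_effect_test(x)
  se <- sd(x) / sqrt(6)
  expect_equal(pt$statistic, mean(x) / se)
  expect_equal(pt$df, 5)
  expect_equal(pt$conf.low, mean(x) - qt(0.975, 5) * se)
  expect_equal(pt$conf.high, mean(x) + qt(0.975, 5) * se)

  # degenerate: identical nonzero effects
  dg <- paired_effect_test(rep(0.1, 8))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$statistic))

  expect_error(paired_effect_test(0.1), class = "tiltchron_input_error")
})

test_that("within-subject SEM removes between-subject offsets", {
  # subjects differing only by a constant offset: SEM exactly 0
  offs <- tibble::tibble(
    subject_id = rep(1:5, each = 2),
    condition = rep(c("a", "b"), 5),
    value = rep(c(0.6, 0.4), 5) + rep(seq(0, 0.4, 0.1), each = 2)
  )
  ws <- within_subject_sem(offs)
  expect_equal(ws$sem, c(0, 0))
  expect_equal(ws$mean, c(0.8, 0.6))

  # hand-computed 3-subject example (independent arithmetic oracle)
  df <- tibble::tibble(
    subject_id = rep(1:3, each = 2),
    condition = rep(c("a", "b"), 3),
    value = c(0.9, 0.5, 0.7, 0.6, 0.8, 0.4)
  )
  grand <- mean(df$value)
  centered <- df$value - rep(tapply(df$value, df$subject_id, mean),
                             each = 2) + grand
  exp_sem_a <- sd(centered[c(1, 3, 5)]) * sqrt(2) / sqrt(3)
  exp_sem_b <- sd(centered[c(2, 4, 6)]) * sqrt(2) / sqrt(3)
  ws2 <- within_subject_sem(df)
  expect_equal(ws2$sem[ws2$condition == "a"], exp_sem_a)
  expect_equal(ws2$sem[ws2$condition == "b"], exp_sem_b)

  # with no between-subject offset variance the Morey-corrected
  # within-subject SEM estimates the ordinary SEM
  set.seed(10)
  big <- tibble::tibble(
    subject_id = rep(1:2000, each = 2),
    condition = rep(c("a", "b"), 2000),
    value = rnorm(4000, mean = rep(c(1, 2), 2000), sd = 0.3)
  )
  wsb <- within_subject_sem(big)
  ordinary <- 0.3 / sqrt(2000)
  expect_lt(abs(wsb$sem[1] - ordinary) / ordinary, 0.06)

  # incomplete subjects are dropped with a warning
  df$value[2] <- NA
  expect_warning(within_subject_sem(df), "dropped")
})

test_that("speed-accuracy correlation and quadrants behave as constructed", {
  a <- c(0.05, 0.1, 0.02, 0.2, 0.12, 0.08, 0.15, 0.01)
  perfect <- speed_accuracy_correlation(a, 2 * a)
  expect_equal(perfect$test$estimate, 1)
  # perfect linearity: all subjects in the low/low and high/high quadrants
  q <- perfect$quadrants
  expect_equal(sum(q$n_subjects[q$accuracy_half == q$rt_half]), 8)

  # independent effects at n = 10,000: r pinned near zero
  set.seed(55)
  acc <- rnorm(10000, 0.15, 0.12)
  rt <- rnorm(10000, 59, 50)
  ind <- speed_accuracy_correlation(acc, rt)
  expect_lt(abs(ind$test$estimate), 0.03)
  expect_true(ind$test$conf.low < 0 & ind$test$conf.high > 0)
  expect_true(all(abs(ind$quadrants$n_subjects - 2500) < 200))

  # n = 3: the Fisher-z interval has no df and is vacuous, not absent
  tiny <- speed_accuracy_correlation(c(0.1, 0.2, 0.05), c(30, 80, 10))
  expect_equal(c(tiny$test$conf.low, tiny$test$conf.high), c(-1, 1))

  dg <- speed_accuracy_correlation(rep(0.1, 5), rnorm(5))
  expect_true(dg$test$degenerate)
  expect_error(speed_accuracy_correlation(a[1:2], a[1:2]),
               class = "tiltchron_input_error")
})

test_that("age regression recovers noiseless slopes and flags df = 0", {
  ages <- c(6, 12, 25, 40, 61, 82)
  eff <- 0.02 + 0.001 * ages
  fit <- age_regression(eff, ages)
  expect_equal(fit$slope, 0.001)
  expect_true(fit$conf.low <= 0.001 & fit$conf.high >= 0.001)

  two <- age_regression(c(0.1, 0.2), c(10, 20))
  expect_true(two$degenerate)
  expect_equal(two$conf.low, -Inf)

  const <- age_regression(rnorm(5), rep(30, 5))
  expect_true(const$degenerate)
})

test_that("cohort_stats assembles, tidies, and prints the full report", {
  set.seed(42)
  n <- 30
  summaries <- tibble::tibble(
    subject_id = 1:n,
    age = round(runif(n, 6, 82)),
    n_missed = rbinom(n, 60, 0.008),
    p_correct_congruent = pmin(runif(n, 0.6, 0.95), 0.99),
    p_correct_incongruent = pmin(runif(n, 0.5, 0.8), 0.99),
    mean_rt_congruent = runif(n, 0.5, 0.8),
    mean_rt_incongruent = runif(n, 0.55, 0.85),
    mean_mt_congruent = runif(n, 0.12, 0.22),
    mean_mt_incongruent = runif(n, 0.12, 0.22),
    flagged = FALSE
  )
  summaries$accuracy_effect <- summaries$p_correct_congruent -
    summaries$p_correct_incongruent
  summaries$rt_effect <- summaries$mean_rt_incongruent -
    summaries$mean_rt_congruent
  summaries$mt_effect <- summaries$mean_mt_congruent -
    summaries$mean_mt_incongruent

  st <- cohort_stats(summaries)
  expect_s3_class(st, "cohort_stats")
  expect_equal(st$n_subjects, n)
  expect_equal(st$accuracy$estimate, mean(summaries$accuracy_effect))
  expect_equal(st$rt_ms$estimate, mean(summaries$rt_effect) * 1000)
  # CIs contain their point estimates
  td <- tidy(st)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_setequal(
    td$term,
    c("accuracy_effect", "rt_effect_ms", "mt_effect_ms", "speed_accuracy_r",
      "age_slope_accuracy", "age_slope_rt_ms"))
  gl <- glance(st)
  expect_equal(gl$n_subjects, n)
  expect_output(print(st), "accuracy effect")

  # flagged subjects are dropped with a warning
  summaries$flagged[1] <- TRUE
  expect_warning(st2 <- cohort_stats(summaries), "dropped")
  expect_equal(st2$n_subjects, n - 1)

  # plots build without error
  p1 <- plot_congruency_effects(summaries[!summaries$flagged, ])
  p2 <- plot_speed_accuracy(summaries)
  p3 <- plot_age_effects(summaries)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  expect_s3_class(p3, "ggplot")
  expect_s3_class(autoplot(st, "speed_accuracy"), "ggplot")
})
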