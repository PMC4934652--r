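#' Summarize one subject's main-phase trials
#'
#' Aggregates a subject's trial results into the two congruence categories
#' (ignoring the specific visual rate): proportion correct per category over
#' responded trials, and mean reaction and movement times per category over
#' correct responded trials only. The accuracy congruency effect is
#' congruent minus incongruent proportion correct; the reaction-time effect
#' is incongruent minus congruent mean RT, so both are positive when
#' congruence helps.
#'
#' @param results Trial-result tibble from [decompose_trials()] (columns
#'   `trial_index`, `reaction_time`, `movement_time`, `missed`, `correct`).
#' @param trials Trial-spec tibble (needs `trial_index`, `phase`,
#'   `congruent`); only main-phase rows are used.
#' @param age Subject age in years.
#' @param subject_id Optional identifier carried into the output.
#'
#' @return A one-row tibble: `subject_id`, `age`, `n_missed`,
#'   `p_correct_congruent`, `p_correct_incongruent`, `mean_rt_congruent`,
#'   `mean_rt_incongruent`, `mean_mt_congruent`, `mean_mt_incongruent`,
#'   `accuracy_effect`, `rt_effect`, `mt_effect` (seconds), and `flagged`
#'   (`TRUE` when some condition has no correct trials, leaving an RT mean
#'   undefined).
#' @export
summarize_subject <- function(results, trials, age = NA_real_,
                              subject_id = NA_integer_) {
  specs <- trials[trials$phase == "main",
                  c("trial_index", "congruent")]
  df <- dplyr::inner_join(specs, results, by = "trial_index")
  if (nrow(df) == 0L) {
    abort("No main-phase trials found in `results`.",
          class = "tiltchron_input_error")
  }
  by_cond <- df |>
    dplyr::filter(!.data$missed) |>
    dplyr::group_by(.data$congruent) |>
    dplyr::summarise(
      p_correct = mean(.data$correct),
      mean_rt = mean(.data$reaction_time[.data$correct]),
      mean_mt = mean(.data$movement_time[.data$correct]),
      n_correct = sum(.data$correct),
      .groups = "drop"
    )
  pick <- function(col, congr) {
    v <- by_cond[[col]][by_cond$congruent == congr]
    if (length(v) == 0L) NA_real_ else v
  }
  out <- tibble::tibble(
    subject_id = subject_id,
    age = age,
    n_missed = sum(df$missed),
    p_correct_congruent = pick("p_correct", TRUE),
    p_correct_incongruent = pick("p_correct", FALSE),
    mean_rt_congruent = pick("mean_rt", TRUE),
    mean_rt_incongruent = pick("mean_rt", FALSE),
    mean_mt_congruent = pick("mean_mt", TRUE),
    mean_mt_incongruent = pick("mean_mt", FALSE)
  )
  out$accuracy_effect <- out$p_correct_congruent - out$p_correct_incongruent
  out$rt_effect <- out$mean_rt_incongruent - out$mean_rt_congruent
  out$mt_effect <- out$mean_mt_congruent - out$mean_mt_incongruent
  out$flagged <- any(is.na(c(out$mean_rt_congruent, out$mean_rt_incongruent)))
  out
}

#' One-sample t test on per-subject congruency effects
#'
#' The cohort-level inference: each subject contributes one
#' congruent-vs-incongruent difference, and the differences are entered into
#' a one-sample, two-sided t test against zero, with a 95 percent confidence
#' interval from the t distribution on `n - 1` degrees of freedom.
#'
#' @param effects Numeric vector of per-subject effects (one per subject).
#' @param conf_level Confidence level (default 0.95).
#'
#' @return A one-row tibble: `estimate` (mean effect), `conf.low`,
#'   `conf.high`, `statistic` (t), `df`, `p.value`, `n`, `degenerate`
#'   (`TRUE` when the effects have zero variance, leaving t undefined).
#' @examples
#' paired_effect_test(c(0.1, 0.2, 0.05, 0.15))
#' @export
paired_effect_test <- function(effects, conf_level = 0.95) {
  effects <- effects[!is.na(effects)]
  n <- length(effects)
  if (n < 2L) {
    abort("Need at least 2 subjects for a one-sample t test.",
          class = "tiltchron_input_error")
  }
  if (sd(effects) == 0) {
    return(tibble::tibble(estimate = mean(effects), conf.low = NA_real_,
                          conf.high = NA_real_, statistic = NA_real_,
                          df = n - 1L, p.value = NA_real_, n = n,
                          degenerate = TRUE))
  }
  tt <- t.test(effects, mu = 0, conf.level = conf_level)
  tibble::tibble(
    estimate = unname(tt$estimate),
    conf.low = tt$conf.int[1],
    conf.high = tt$conf.int[2],
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    n = n,
    degenerate = FALSE
  )
}

#' Within-subject standard errors of the mean
#'
#' Error bars appropriate for a repeated-measures contrast: each subject's
#' overall mean is removed (Cousineau normalization, adding back the grand
#' mean) and the per-condition SEM of the normalized values is inflated by
#' Morey's bias-correction factor `sqrt(J / (J - 1))` for `J` conditions.
#' Subjects with a missing condition are dropped with a warning.
#'
#' @param data A data frame in long format.
#' @param subject,condition,value Column names (strings) identifying the
#'   subject, the within-subject condition, and the measured value.
#'
#' @return A tibble with one row per condition: `condition`, `mean`, `sem`,
#'   `n`.
#' @export
within_subject_sem <- function(data, subject = "subject_id",
                               condition = "condition", value = "value") {
  df <- tibble::tibble(
    subject = data[[subject]],
    condition = data[[condition]],
    value = data[[value]]
  )
  n_cond <- dplyr::n_distinct(df$condition)
  complete <- df |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::count(.data$subject) |>
    dplyr::filter(.data$n == n_cond)
  dropped <- dplyr::n_distinct(df$subject) - nrow(complete)
  if (dropped > 0) {
    warn(sprintf("%d subject(s) dropped: incomplete condition data.", dropped))
    df <- df[df$subject %in% complete$subject, ]
  }
  grand <- mean(df$value)
  morey <- sqrt(n_cond / (n_cond - 1))
  df |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(centered = .data$value - mean(.data$value) + grand) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = sd(.data$centered) * morey / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Speed-accuracy correlation across subjects
#'
#' Tests whether subjects traded speed for accuracy: Pearson correlation
#' between the accuracy-defined and the RT-defined congruency effects, with
#' a Fisher-z 95 percent confidence interval, plus a median-split quadrant
#' diagnostic — under independence the subjects scatter about equally over
#' the four quadrants formed by the two medians.
#'
#' @param accuracy_effects,rt_effects Paired numeric vectors, one value per
#'   subject.
#' @param conf_level Confidence level (default 0.95).
#'
#' @return A list with `test` (one-row tibble: `estimate`, `conf.low`,
#'   `conf.high`, `p.value`, `n`, `degenerate`) and `quadrants` (tibble of
#'   median-split counts).
#' @export
speed_accuracy_correlation <- function(accuracy_effects, rt_effects,
                                       conf_level = 0.95) {
  ok <- !is.na(accuracy_effects) & !is.na(rt_effects)
  a <- accuracy_effects[ok]
  r <- rt_effects[ok]
  if (length(a) < 3L) {
    abort("Need at least 3 paired observations.",
          class = "tiltchron_input_error")
  }
  if (sd(a) == 0 || sd(r) == 0) {
    return(list(
      test = tibble::tibble(estimate = NA_real_, conf.low = NA_real_,
                            conf.high = NA_real_, p.value = NA_real_,
                            n = length(a), degenerate = TRUE),
      quadrants = NULL
    ))
  }
  ct <- cor.test(a, r, method = "pearson", conf.level = conf_level)
  # cor.test omits the Fisher-z interval at n = 3 (zero z-scale df):
  # the interval is then vacuous
  ci <- ct$conf.int %||% c(-1, 1)
  quad <- tibble::tibble(
    accuracy_half = ifelse(a > median(a), "high", "low"),
    rt_half = ifelse(r > median(r), "high", "low")
  ) |>
    dplyr::count(.data$accuracy_half, .data$rt_half, name = "n_subjects")
  list(
    test = tibble::tibble(
      estimate = unname(ct$estimate),
      conf.low = ci[1],
      conf.high = ci[2],
      p.value = ct$p.value,
      n = length(a),
      degenerate = FALSE
    ),
    quadrants = quad
  )
}

#' Regression of a congruency effect on age
#'
#' Ordinary least-squares slope of the per-subject effect on age, with a
#' two-sided p value and 95 percent confidence interval on the slope. Used
#' to ask whether audiovisual interaction changes across the lifespan.
#'
#' @param effects Per-subject effect values.
#' @param ages Ages in years (same length).
#' @param conf_level Confidence level (default 0.95).
#'
#' @return A one-row tibble: `slope`, `conf.low`, `conf.high`, `p.value`,
#'   `n`, `degenerate` (`TRUE` when the fit leaves no residual degrees of
#'   freedom or ages are constant).
#' @export
age_regression <- function(effects, ages, conf_level = 0.95) {
  ok <- !is.na(effects) & !is.na(ages)
  y <- effects[ok]
  x <- ages[ok]
  if (length(y) < 2L) {
    abort("Need at least 2 observations.", class = "tiltchron_input_error")
  }
  if (sd(x) == 0) {
    return(tibble::tibble(slope = NA_real_, conf.low = NA_real_,
                          conf.high = NA_real_, p.value = NA_real_,
                          n = length(y), degenerate = TRUE))
  }
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  if (fit$df.residual < 1L) {
    return(tibble::tibble(slope = slope, conf.low = -Inf, conf.high = Inf,
                          p.value = NA_real_, n = length(y),
                          degenerate = TRUE))
  }
  ci <- confint(fit, "x", level = conf_level)
  p <- summary(fit)$coefficients["x", "Pr(>|t|)"]
  tibble::tibble(slope = slope, conf.low = ci[1], conf.high = ci[2],
                 p.value = p, n = length(y), degenerate = FALSE)
}

#' Cohort-level congruency statistics
#'
#' Assembles the full set of cohort statistics from per-subject summaries:
#' one-sample t tests on the accuracy, reaction-time, and movement-time
#' congruency effects (RT and MT reported in milliseconds), per-condition
#' within-subject SEMs, the speed-accuracy correlation with quadrant
#' diagnostic, and age regressions for both effect measures.
#'
#' @param summaries Tibble of per-subject summaries (rows from
#'   [summarize_subject()]); subjects flagged for an undefined RT mean are
#'   dropped from the chronometric tests with a warning.
#' @param conf_level Confidence level (default 0.95).
#'
#' @return An object of class `cohort_stats`: a list with elements
#'   `n_subjects`, `accuracy` / `rt_ms` / `mt_ms` (paired-test tibbles),
#'   `mt_means_ms`, `sem_accuracy`, `sem_rt_ms`, `speed_accuracy`,
#'   `quadrants`, `age_accuracy`, `age_rt_ms`, `n_missed_total`, and
#'   `summaries`.
#' @export
cohort_stats <- function(summaries, conf_level = 0.95) {
  if (any(summaries$flagged, na.rm = TRUE)) {
    warn(sprintf("%d subject(s) with an undefined condition RT mean dropped.",
                 sum(summaries$flagged, na.rm = TRUE)))
    summaries <- summaries[!summaries$flagged, ]
  }
  acc <- paired_effect_test(summaries$accuracy_effect, conf_level)
  rt <- paired_effect_test(summaries$rt_effect * 1000, conf_level)
  mt <- paired_effect_test(summaries$mt_effect * 1000, conf_level)
  sem_acc <- within_subject_sem(
    tidyr::pivot_longer(
      summaries[, c("subject_id", "p_correct_congruent",
                    "p_correct_incongruent")],
      -"subject_id", names_to = "condition", values_to = "value",
      names_prefix = "p_correct_"),
    subject = "subject_id")
  sem_rt <- within_subject_sem(
    tidyr::pivot_longer(
      summaries[, c("subject_id", "mean_rt_congruent",
                    "mean_rt_incongruent")],
      -"subject_id", names_to = "condition", values_to = "value",
      names_prefix = "mean_rt_"),
    subject = "subject_id")
  sem_rt$mean <- sem_rt$mean * 1000
  sem_rt$sem <- sem_rt$sem * 1000
  sac <- speed_accuracy_correlation(summaries$accuracy_effect,
                                    summaries$rt_effect * 1000, conf_level)
  structure(
    list(
      n_subjects = nrow(summaries),
      accuracy = acc,
      rt_ms = rt,
      mt_ms = mt,
      mt_means_ms = tibble::tibble(
        condition = c("congruent", "incongruent"),
        mean_mt_ms = c(mean(summaries$mean_mt_congruent) * 1000,
                       mean(summaries$mean_mt_incongruent) * 1000)
      ),
      sem_accuracy = sem_acc,
      sem_rt_ms = sem_rt,
      speed_accuracy = sac$test,
      quadrants = sac$quadrants,
      age_accuracy = age_regression(summaries$accuracy_effect,
                                    summaries$age, conf_level),
      age_rt_ms = age_regression(summaries$rt_effect * 1000,
                                 summaries$age, conf_level),
      n_missed_total = sum(summaries$n_missed),
      summaries = summaries
    ),
    class = "cohort_stats"
  )
}

#' @export
print.cohort_stats <- function(x, ...) {
  fmt_test <- function(t, unit = "") {
    sprintf("%.4g%s (95%% CI [%.4g, %.4g]), t(%d) = %.3g, p = %.3g",
            t$estimate, unit, t$conf.low, t$conf.high, t$df, t$statistic,
            t$p.value)
  }
  cat(sprintf("<cohort_stats> n = %d subjects, %d missed trials\n",
              x$n_subjects, x$n_missed_total))
  cat("  accuracy effect (congruent - incongruent): ",
      fmt_test(x$accuracy), "\n", sep = "")
  cat("  reaction-time effect (incongruent - congruent): ",
      fmt_test(x$rt_ms, " ms"), "\n", sep = "")
  cat(sprintf("  movement time: congruent %.4g ms, incongruent %.4g ms; diff %s\n",
              x$mt_means_ms$mean_mt_ms[1], x$mt_means_ms$mean_mt_ms[2],
              fmt_test(x$mt_ms, " ms")))
  cat(sprintf("  speed-accuracy correlation: r = %.3g (95%% CI [%.3g, %.3g])\n",
              x$speed_accuracy$estimate, x$speed_accuracy$conf.low,
              x$speed_accuracy$conf.high))
  cat(sprintf("  age slope, accuracy effect: %.3g /yr (95%% CI [%.3g, %.3g]), p = %.3g\n",
              x$age_accuracy$slope, x$age_accuracy$conf.low,
              x$age_accuracy$conf.high, x$age_accuracy$p.value))
  cat(sprintf("  age slope, RT effect: %.3g ms/yr (95%% CI [%.3g, %.3g]), p = %.3g\n",
              x$age_rt_ms$slope, x$age_rt_ms$conf.low, x$age_rt_ms$conf.high,
              x$age_rt_ms$p.value))
  invisible(x)
}

#' Tidy a cohort_stats object
#'
#' @param x A [cohort_stats()] object.
#' @param ... Unused.
#' @return A tibble with one row per cohort-level estimate (`term`,
#'   `estimate`, `conf.low`, `conf.high`, `statistic`, `df`, `p.value`).
#' @exportS3Method generics::tidy
tidy.cohort_stats <- function(x, ...) {
  row <- function(term, t) {
    tibble::tibble(term = term, estimate = t$estimate,
                   conf.low = t$conf.low, conf.high = t$conf.high,
                   statistic = t$statistic %||% NA_real_,
                   df = t$df %||% NA_real_, p.value = t$p.value)
  }
  dplyr::bind_rows(
    row("accuracy_effect", x$accuracy),
    row("rt_effect_ms", x$rt_ms),
    row("mt_effect_ms", x$mt_ms),
    tibble::tibble(term = "speed_accuracy_r",
                   estimate = x$speed_accuracy$estimate,
                   conf.low = x$speed_accuracy$conf.low,
                   conf.high = x$speed_accuracy$conf.high,
                   statistic = NA_real_, df = NA_real_,
                   p.value = x$speed_accuracy$p.value),
    tibble::tibble(term = "age_slope_accuracy",
                   estimate = x$age_accuracy$slope,
                   conf.low = x$age_accuracy$conf.low,
                   conf.high = x$age_accuracy$conf.high,
                   statistic = NA_real_, df = NA_real_,
                   p.value = x$age_accuracy$p.value),
    tibble::tibble(term = "age_slope_rt_ms",
                   estimate = x$age_rt_ms$slope,
                   conf.low = x$age_rt_ms$conf.low,
                   conf.high = x$age_rt_ms$conf.high,
                   statistic = NA_real_, df = NA_real_,
                   p.value = x$age_rt_ms$p.value)
  )
}

#' Glance at a cohort_stats object
#'
#' @inheritParams tidy.cohort_stats
#' @return A one-row tibble of headline cohort quantities.
#' @exportS3Method generics::glance
glance.cohort_stats <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    accuracy_effect = x$accuracy$estimate,
    accuracy_t = x$accuracy$statistic,
    rt_effect_ms = x$rt_ms$estimate,
    rt_t = x$rt_ms$statistic,
    mt_effect_ms = x$mt_ms$estimate,
    mt_t = x$mt_ms$statistic,
    speed_accuracy_r = x$speed_accuracy$estimate,
    n_missed_total = x$n_missed_total
  )
}
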