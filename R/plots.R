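#' Plot per-condition means with within-subject error bars
#'
#' Accuracy and reaction time by congruence condition, with within-subject
#' (Cousineau-Morey) standard errors of the mean.
#'
#' @param summaries Per-subject summary tibble (see [summarize_subject()]).
#' @return A ggplot object.
#' @export
plot_congruency_effects <- function(summaries) {
  acc <- within_subject_sem(
    tidyr::pivot_longer(
      summaries[, c("subject_id", "p_correct_congruent",
                    "p_correct_incongruent")],
      -"subject_id", names_to = "condition", values_to = "value",
      names_prefix = "p_correct_"),
    subject = "subject_id")
  acc$measure <- "Proportion correct"
  rt <- within_subject_sem(
    tidyr::pivot_longer(
      summaries[, c("subject_id", "mean_rt_congruent",
                    "mean_rt_incongruent")],
      -"subject_id", names_to = "condition", values_to = "value",
      names_prefix = "mean_rt_"),
    subject = "subject_id")
  rt$mean <- rt$mean * 1000
  rt$sem <- rt$sem * 1000
  rt$measure <- "Reaction time (ms)"
  df <- dplyr::bind_rows(acc, rt)
  df$condition <- factor(df$condition, c("congruent", "incongruent"),
                         c("Congruent", "Incongruent"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.15) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  caption = "Error bars: within-subject SEM") +
    ggplot2::theme_minimal()
}

#' Plot the speed-accuracy relationship across subjects
#'
#' One point per subject: the RT-defined congruency effect against the
#' accuracy-defined effect, with median-split lines dividing the plane into
#' the four quadrants used for the independence diagnostic.
#'
#' @inheritParams plot_congruency_effects
#' @return A ggplot object.
#' @export
plot_speed_accuracy <- function(summaries) {
  df <- summaries[!is.na(summaries$accuracy_effect) &
                    !is.na(summaries$rt_effect), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy_effect,
                                   y = .data$rt_effect * 1000)) +
    ggplot2::geom_vline(xintercept = median(df$accuracy_effect),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = median(df$rt_effect * 1000),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Congruency effect: accuracy (prop. correct)",
                  y = "Congruency effect: reaction time (ms)") +
    ggplot2::theme_minimal()
}

#' Plot congruency effects against age
#'
#' Per-subject accuracy and RT congruency effects as a function of age, with
#' OLS fit lines.
#'
#' @inheritParams plot_congruency_effects
#' @return A ggplot object.
#' @export
plot_age_effects <- function(summaries) {
  df <- dplyr::bind_rows(
    tibble::tibble(age = summaries$age, effect = summaries$accuracy_effect,
                   measure = "Accuracy effect"),
    tibble::tibble(age = summaries$age, effect = summaries$rt_effect * 1000,
                   measure = "RT effect (ms)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$effect)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "black", linewidth = 0.5) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Age (years)", y = "Congruency effect") +
    ggplot2::theme_minimal()
}

#' Autoplot a cohort_stats object
#'
#' @param object A [cohort_stats()] object.
#' @param type One of `"effects"`, `"speed_accuracy"`, `"age"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_stats <- function(object,
                                  type = c("effects", "speed_accuracy",
                                           "age"), ...) {
  type <- match.arg(type)
  switch(type,
         effects = plot_congruency_effects(object$summaries),
         speed_accuracy = plot_speed_accuracy(object$summaries),
         age = plot_age_effects(object$summaries))
}
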