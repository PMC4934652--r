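#' Decompose every subject's traces in a cohort
#'
#' Runs QC and chronometric decomposition over all subjects of a simulated
#' (or loaded) cohort.
#'
#' @param cohort A `cohort_sim` (or a compatible list with `traces`, `plans`,
#'   `config`).
#' @param threshold,epsilon,direction_mode See [decompose_trials()].
#' @param qc_sample_frac,qc_trial_frac See [qc_subject()].
#'
#' @return A list: `results` (tibble of trial results with `subject_id`) and
#'   `qc` (tibble with `subject_id`, `usable`, `prop_jittery_trials`).
#' @export
decompose_cohort <- function(cohort, threshold = NULL, epsilon = 0.5,
                             direction_mode = "velocity",
                             qc_sample_frac = 0.25, qc_trial_frac = 0.5) {
  cfg <- cohort$config
  threshold <- threshold %||% cfg$tilt_threshold
  ids <- as.integer(names(cohort$traces))
  res <- vector("list", length(ids))
  qc <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    mat <- cohort$traces[[i]]
    specs <- cohort$plans[[i]]$trials
    r <- decompose_trials(mat, specs, threshold = threshold,
                          epsilon = epsilon,
                          direction_mode = direction_mode,
                          sample_rate = cfg$sample_rate)
    r$subject_id <- ids[i]
    res[[i]] <- r
    q <- qc_subject(mat, threshold = threshold, epsilon = epsilon,
                    sample_frac = qc_sample_frac, trial_frac = qc_trial_frac)
    q$subject_id <- ids[i]
    qc[[i]] <- q
  }
  list(
    results = dplyr::bind_rows(res) |> dplyr::relocate("subject_id"),
    qc = dplyr::bind_rows(qc) |> dplyr::relocate("subject_id")
  )
}

#' Summarize every usable subject in a cohort
#'
#' Applies [summarize_subject()] to each subject that passed trace QC and,
#' when practice information is available, passed the practice gate.
#'
#' @param decomposed Output of [decompose_cohort()].
#' @param cohort The cohort the results came from (for plans, ages, and
#'   practice status).
#'
#' @return A tibble of per-subject summaries (one row per included subject).
#' @export
summarize_cohort <- function(decomposed, cohort) {
  usable <- decomposed$qc$subject_id[decomposed$qc$usable]
  if ("practice_status" %in% names(cohort$subjects)) {
    passed <- cohort$subjects$subject_id[
      cohort$subjects$practice_status == "pass"]
    usable <- intersect(usable, passed)
  }
  purrr::map_dfr(usable, function(id) {
    summarize_subject(
      decomposed$results[decomposed$results$subject_id == id, ],
      cohort$plans[[as.character(id)]]$trials,
      age = cohort$subjects$age[cohort$subjects$subject_id == id],
      subject_id = id
    )
  })
}

#' Run the full analysis pipeline on a cohort
#'
#' Chronometric decomposition, QC exclusion, per-subject aggregation, and
#' cohort statistics, in one call.
#'
#' @inheritParams decompose_cohort
#' @return A list: `results`, `qc`, `summaries`, `stats` (a
#'   [cohort_stats()] object).
#' @examples
#' cohort <- simulate_cohort(n_subjects = 8, master_seed = 3)
#' fit <- analyze_cohort(cohort)
#' glance(fit$stats)
#' @export
analyze_cohort <- function(cohort, threshold = NULL, epsilon = 0.5,
                           direction_mode = "velocity",
                           qc_sample_frac = 0.25, qc_trial_frac = 0.5) {
  dec <- decompose_cohort(cohort, threshold = threshold, epsilon = epsilon,
                          direction_mode = direction_mode,
                          qc_sample_frac = qc_sample_frac,
                          qc_trial_frac = qc_trial_frac)
  summaries <- summarize_cohort(dec, cohort)
  if (nrow(summaries) == 0L) {
    abort("No usable subjects after QC; cannot compute cohort statistics.",
          class = "tiltchron_input_error")
  }
  list(results = dec$results, qc = dec$qc, summaries = summaries,
       stats = cohort_stats(summaries))
}

#' Compare recovered chronometry against simulated ground truth
#'
#' Joins the decomposition output with the generator's latent trial values,
#' for validating that reaction and movement times are recovered on the
#' sampling grid.
#'
#' @param cohort A `cohort_sim`.
#' @param results Results tibble from [decompose_cohort()].
#'
#' @return A tibble with one row per main trial: injected `decision_time`,
#'   `movement_duration`, `missed` alongside recovered `reaction_time`,
#'   `movement_time`, plus `rt_error` and `mt_error` (recovered minus
#'   injected, seconds).
#' @export
recovery_table <- function(cohort, results) {
  truth <- cohort$latent[cohort$latent$phase == "main",
                         c("subject_id", "trial_index", "missed",
                           "correct", "decision_time", "movement_duration",
                           "response_direction")]
  dplyr::inner_join(truth, results,
                    by = c("subject_id", "trial_index"),
                    suffix = c("_true", "_est")) |>
    dplyr::mutate(
      rt_error = .data$reaction_time - .data$decision_time,
      mt_error = .data$movement_time - .data$movement_duration
    )
}
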