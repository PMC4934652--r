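#' Behavioral parameters of a synthetic player
#'
#' The generative model is descriptive: correctness is Bernoulli with a
#' congruence-dependent probability, reaction time (decision onset) is
#' lognormal with a congruence-dependent log-mean, and movement time is
#' normal truncated at zero and independent of congruence. Defaults are
#' calibrated to the cohort-level values the design targets: accuracy
#' 0.80 vs 0.65 (congruency effect 0.15), mean reaction times 650 vs
#' 709.21 ms (effect 59.21 ms), movement time 170 +/- 40 ms in both
#' conditions, and a 0.8 percent deadline-miss rate.
#'
#' @param p_correct_congruent,p_correct_incongruent Probability of a correct
#'   classification on congruent / incongruent trials.
#' @param rt_mean_congruent,rt_mean_incongruent Mean reaction time in seconds
#'   per condition; converted internally to lognormal log-means with log-sd
#'   `rt_sigma`.
#' @param rt_sigma Log-scale standard deviation of the reaction-time
#'   lognormal (default 0.25).
#' @param mt_mean,mt_sd Movement-time mean and sd in seconds (identical
#'   across congruence).
#' @param tremor_sd Standard deviation in degrees of pre-decision hand
#'   tremor in the rendered tilt trace.
#' @param miss_rate Probability of failing to beat the response deadline.
#' @param jiggler Logical; a player who continuously jiggles the tablet,
#'   producing unusable traces.
#' @param age Age in years (minimum 6).
#'
#' @return An object of class `subject_params` (a one-row tibble).
#' @export
subject_params <- function(p_correct_congruent = 0.80,
                           p_correct_incongruent = 0.65,
                           rt_mean_congruent = 0.650,
                           rt_mean_incongruent = 0.70921,
                           rt_sigma = 0.25,
                           mt_mean = 0.170,
                           mt_sd = 0.040,
                           tremor_sd = 0.10,
                           miss_rate = 0.008,
                           jiggler = FALSE,
                           age = 30) {
  p <- tibble::tibble(
    p_correct_congruent = p_correct_congruent,
    p_correct_incongruent = p_correct_incongruent,
    rt_mean_congruent = rt_mean_congruent,
    rt_mean_incongruent = rt_mean_incongruent,
    rt_sigma = rt_sigma, mt_mean = mt_mean, mt_sd = mt_sd,
    tremor_sd = tremor_sd, miss_rate = miss_rate,
    jiggler = jiggler, age = age
  )
  validate_subject_params(p)
  class(p) <- c("subject_params", class(p))
  p
}

validate_subject_params <- function(p) {
  probs <- c(p$p_correct_congruent, p$p_correct_incongruent, p$miss_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("Probabilities must lie in [0, 1].", class = "tiltchron_input_error")
  }
  if (any(p$mt_mean <= 0) || any(p$mt_sd < 0) ||
      any(p$rt_mean_congruent <= 0) || any(p$rt_mean_incongruent <= 0) ||
      any(p$rt_sigma <= 0)) {
    abort("Time parameters must be positive.", class = "tiltchron_input_error")
  }
  if (any(p$tremor_sd < 0)) {
    abort("`tremor_sd` must be non-negative.", class = "tiltchron_input_error")
  }
  if (any(p$age < 6)) {
    abort("`age` must be at least 6 years.", class = "tiltchron_input_error")
  }
  invisible(p)
}

# lognormal log-mean giving arithmetic mean m at log-sd sigma
lnorm_mu <- function(m, sigma) log(m) - sigma^2 / 2

#' Population distribution over subject parameters
#'
#' Describes the between-subject distribution from which a cohort is drawn.
#' Per subject, a baseline accuracy and an accuracy congruency effect are
#' drawn and converted to per-condition probabilities (clamped to
#' [0.05, 0.995]); a congruent-condition mean reaction time and an RT
#' congruency effect are drawn and converted to per-condition lognormal
#' means; movement time is congruence-independent. Ages are uniform over
#' 6-82 years and, by default, unrelated to the effects. One of 60 players
#' is, on average, a "jiggler" whose traces are unusable.
#'
#' @param accuracy_effect_mean,accuracy_effect_sd Mean and between-subject sd
#'   of the accuracy congruency effect (congruent minus incongruent
#'   proportion correct).
#' @param accuracy_base_mean,accuracy_base_sd Mean and sd of the
#'   subject-level average proportion correct.
#' @param rt_effect_mean,rt_effect_sd Mean and between-subject sd, in
#'   seconds, of the reaction-time congruency effect (incongruent minus
#'   congruent).
#' @param rt_base_mean,rt_base_sd Mean and sd, in seconds, of the congruent
#'   condition's mean reaction time.
#' @param rt_sigma Within-subject lognormal log-sd of reaction times.
#' @param mt_mean_mean,mt_mean_sd Between-subject distribution of the
#'   movement-time mean (seconds).
#' @param mt_sd Within-subject movement-time sd (seconds).
#' @param tremor_range Range (degrees) of the uniform tremor-sd draw.
#' @param miss_rate Deadline-miss probability (default 0.008, i.e. 28 misses
#'   expected in 3,600 presentations).
#' @param jiggler_prob Probability a subject is a jiggler (default 1/60).
#' @param age_range Age range in years (default 6-82).
#'
#' @return An object of class `cohort_population` (a named list).
#' @export
cohort_population <- function(accuracy_effect_mean = 0.15,
                              accuracy_effect_sd = 0.12,
                              accuracy_base_mean = 0.725,
                              accuracy_base_sd = 0.06,
                              rt_effect_mean = 0.05921,
                              rt_effect_sd = 0.050,
                              rt_base_mean = 0.650,
                              rt_base_sd = 0.080,
                              rt_sigma = 0.25,
                              mt_mean_mean = 0.170,
                              mt_mean_sd = 0.030,
                              mt_sd = 0.040,
                              tremor_range = c(0.05, 0.20),
                              miss_rate = 0.008,
                              jiggler_prob = 1 / 60,
                              age_range = c(6, 82)) {
  structure(as.list(environment()), class = "cohort_population")
}

#' Draw subject parameters from a population
#'
#' @param population A [cohort_population()].
#' @param n Number of subjects.
#' @param seed Integer seed.
#'
#' @return A tibble with one row per subject: `subject_id` plus every
#'   [subject_params()] field.
#' @export
sample_subject_params <- function(population = cohort_population(), n,
                                  seed) {
  stopifnot(inherits(population, "cohort_population"), n >= 1)
  p <- population
  local_seed(seed, {
    base_acc <- rnorm(n, p$accuracy_base_mean, p$accuracy_base_sd)
    eff_acc <- rnorm(n, p$accuracy_effect_mean, p$accuracy_effect_sd)
    clamp01 <- function(x) pmin(pmax(x, 0.05), 0.995)
    rt_base <- pmax(rnorm(n, p$rt_base_mean, p$rt_base_sd), 0.30)
    eff_rt <- rnorm(n, p$rt_effect_mean, p$rt_effect_sd)
    mtm <- pmax(rnorm(n, p$mt_mean_mean, p$mt_mean_sd), 0.08)
    tibble::tibble(
      subject_id = seq_len(n),
      p_correct_congruent = clamp01(base_acc + eff_acc / 2),
      p_correct_incongruent = clamp01(base_acc - eff_acc / 2),
      rt_mean_congruent = rt_base,
      rt_mean_incongruent = pmax(rt_base + eff_rt, 0.15),
      rt_sigma = p$rt_sigma,
      mt_mean = mtm,
      mt_sd = p$mt_sd,
      tremor_sd = runif(n, p$tremor_range[1], p$tremor_range[2]),
      miss_rate = p$miss_rate,
      jiggler = runif(n) < p$jiggler_prob,
      age = round(runif(n, p$age_range[1], p$age_range[2]))
    )
  })
}

#' Sample latent trial outcomes for one subject
#'
#' Draws, for each trial of a plan, the hidden ground truth: correctness
#' (Bernoulli with the congruence-appropriate probability; no-sound practice
#' trials use the congruent probability since no auditory interference is
#' present), decision time (lognormal), movement duration (normal truncated
#' at zero), the implied tilt direction (toward for a "bad" judgment, away
#' for "good"), and whether the deadline was missed. Latent times are
#' redrawn until the threshold crossing fits inside the response window on
#' the 60 Hz grid, so `decision_time + movement_duration` always beats the
#' deadline on responded trials.
#'
#' @param trials Trials tibble from a [build_session_plan()] (columns
#'   `trial_index`, `congruent`, `species`).
#' @param params A [subject_params()] row.
#' @param config A [session_config()].
#' @param seed Integer seed.
#'
#' @return The `trials` tibble with added columns `missed`, `correct`,
#'   `decision_time`, `movement_duration`, `response_direction`.
#' @export
sample_latent_trials <- function(trials, params, config = session_config(),
                                 seed) {
  validate_subject_params(params)
  n <- nrow(trials)
  sr <- config$sample_rate
  n_samples <- round(config$response_deadline * sr)
  congruent <- trials$congruent
  congruent[is.na(congruent)] <- TRUE   # no-sound: no interference

  local_seed(seed, {
    missed <- runif(n) < params$miss_rate
    p_corr <- ifelse(congruent, params$p_correct_congruent,
                     params$p_correct_incongruent)
    correct <- runif(n) < p_corr
    mu <- ifelse(congruent,
                 lnorm_mu(params$rt_mean_congruent, params$rt_sigma),
                 lnorm_mu(params$rt_mean_incongruent, params$rt_sigma))
    dec <- rlnorm(n, mu, params$rt_sigma)
    mt <- abs(rnorm(n, params$mt_mean, params$mt_sd))
    # redraw latent times until the crossing sample fits in the window
    for (iter in 1:100) {
      d_s <- round(dec * sr)
      c_s <- d_s + round(mt * sr)
      bad <- !missed & (d_s < 1 | c_s > n_samples - 1)
      if (!any(bad)) break
      dec[bad] <- rlnorm(sum(bad), mu[bad], params$rt_sigma)
      mt[bad] <- abs(rnorm(sum(bad), params$mt_mean, params$mt_sd))
    }
    still_bad <- !missed & (round(dec * sr) < 1 |
                              round(dec * sr) + round(mt * sr) > n_samples - 1)
    missed <- missed | still_bad

    judged_bad <- ifelse(correct, trials$species == "bad",
                         trials$species == "good")
    direction <- ifelse(judged_bad, "toward", "away")

    out <- trials
    out$missed <- missed
    out$correct <- ifelse(missed, NA, correct)
    out$decision_time <- ifelse(missed, NA_real_, dec)
    out$movement_duration <- ifelse(missed, NA_real_, mt)
    out$response_direction <- ifelse(missed, "none", direction)
    out
  })
}

# Tremor samples bounded so sample-to-sample changes stay strictly below
# epsilon: values clipped to +/- (epsilon/2 - tiny).
bounded_tremor <- function(n, tremor_sd, epsilon) {
  if (tremor_sd <= 0 || n <= 0) return(numeric(n))
  bound <- epsilon / 2 - 1e-9
  pmin(pmax(rnorm(n, sd = tremor_sd), -bound), bound)
}

#' Render 60 Hz tilt traces from latent trials
#'
#' Inverts the chronometric decomposition: each responded trial's trace is
#' zero-mean bounded tremor up to the decision sample, then a linear ramp in
#' the response direction that reaches the 17 degree threshold exactly
#' `movement_duration` after `decision_time` (both rounded to the 60 Hz
#' grid) and continues along the same slope, capped at `cap` degrees.
#' Missed trials contain tremor only. Jiggler subjects produce
#' high-amplitude quasi-sinusoidal wobble throughout every trial. Tremor is
#' clipped to `epsilon / 2` so that no tremor-only sample-to-sample change
#' can reach the chronometry module's noise floor: bounded tremor can
#' neither mimic movement onset nor inject reversals.
#'
#' @param latent Tibble from [sample_latent_trials()].
#' @param config A [session_config()].
#' @param tremor_sd Tremor standard deviation in degrees.
#' @param jiggler Logical; render unusable wobble instead.
#' @param seed Integer seed.
#' @param epsilon Chronometry noise tolerance the tremor must stay below
#'   (default 0.5).
#' @param cap Tilt magnitude cap in degrees (default 75).
#'
#' @return A numeric matrix with `round(response_deadline * sample_rate)`
#'   rows (samples; row 1 is sample 0, the onset baseline, always 0) and one
#'   column per trial, column names = `trial_index`.
#' @export
render_tilt_traces <- function(latent, config = session_config(),
                               tremor_sd = 0.1, jiggler = FALSE, seed,
                               epsilon = 0.5, cap = 75) {
  sr <- config$sample_rate
  n_samples <- round(config$response_deadline * sr)
  n_trials <- nrow(latent)
  thr <- config$tilt_threshold
  local_seed(seed, {
    mat <- matrix(0, nrow = n_samples, ncol = n_trials)
    if (jiggler) {
      t <- (seq_len(n_samples) - 1L) / sr
      for (j in seq_len(n_trials)) {
        amp <- runif(1, 0.5 * thr, 0.85 * thr)
        f <- runif(1, 2, 4)
        ph <- runif(1, 0, 2 * pi)
        mat[, j] <- amp * sin(2 * pi * f * t + ph) - amp * sin(ph) +
          rnorm(n_samples, sd = 1)
        mat[1, j] <- 0
      }
    } else {
      for (j in seq_len(n_trials)) {
        if (latent$missed[j]) {
          mat[2:n_samples, j] <- bounded_tremor(n_samples - 1L, tremor_sd,
                                                epsilon)
          next
        }
        d <- round(latent$decision_time[j] * sr)
        m <- round(latent$movement_duration[j] * sr)
        cc <- d + m
        if (d < 1 || cc > n_samples - 1) {
          abort(sprintf("Latent times of trial %d exceed the response window.",
                        latent$trial_index[j]),
                class = "tiltchron_input_error")
        }
        dsign <- if (latent$response_direction[j] == "toward") 1 else -1
        if (d > 1) {
          mat[2:d, j] <- bounded_tremor(d - 1L, tremor_sd, epsilon)
        }
        k <- d:(n_samples - 1L)          # 0-based samples on/after onset
        ramp <- thr * (k - d + 1) / (m + 1)
        mat[k + 1L, j] <- dsign * pmin(ramp, cap)
      }
    }
    colnames(mat) <- latent$trial_index
    mat
  })
}

# matrix -> long tibble (trial_index, sample_index, tilt_deg)
traces_as_tibble <- function(mat) {
  tibble::tibble(
    trial_index = rep(as.integer(colnames(mat)), each = nrow(mat)),
    sample_index = rep(seq_len(nrow(mat)) - 1L, times = ncol(mat)),
    tilt_deg = as.vector(mat)
  )
}

#' Simulate a full cohort
#'
#' Generates a complete synthetic data set: per subject, a seeded session
#' plan, latent practice and main-phase outcomes, the practice gate
#' decision (subjects below threshold on a second randomized block are
#' excluded), and rendered main-phase tilt traces. Ground truth is kept
#' separate from the observable traces. Everything is deterministic in
#' `master_seed`.
#'
#' @param n_subjects Number of subjects (default 60).
#' @param population A [cohort_population()].
#' @param master_seed Integer master seed.
#' @param config A [session_config()].
#'
#' @return An object of class `cohort_sim`: a list with
#'   \describe{
#'     \item{subjects}{tibble of drawn parameters plus `practice_status`.}
#'     \item{plans}{list of `session_plan`s, one per subject.}
#'     \item{latent}{long tibble of ground truth for every trial
#'       (`subject_id`, trial spec columns, `missed`, `correct`,
#'       `decision_time`, `movement_duration`, `response_direction`).}
#'     \item{traces}{named list of main-phase trace matrices (see
#'       [render_tilt_traces()]), one per subject.}
#'     \item{config, population, master_seed}{inputs, for replay.}
#'   }
#' @examples
#' cohort <- simulate_cohort(n_subjects = 2, master_seed = 7)
#' dplyr::count(cohort$latent, subject_id, phase)
#' @export
simulate_cohort <- function(n_subjects = 60,
                            population = cohort_population(),
                            master_seed = 1,
                            config = session_config()) {
  stopifnot(n_subjects >= 1)
  seeds <- derive_seeds(master_seed, 4L * n_subjects + 1L)
  subjects <- sample_subject_params(population, n_subjects, seeds[1L])

  plans <- vector("list", n_subjects)
  latent_list <- vector("list", n_subjects)
  traces <- vector("list", n_subjects)
  status <- character(n_subjects)

  for (i in seq_len(n_subjects)) {
    s <- seeds[(4L * (i - 1L) + 2L):(4L * (i - 1L) + 5L)]
    params <- subjects[i, ]
    plan <- build_session_plan(config, seed = s[1L])
    plans[[i]] <- plan
    lat <- sample_latent_trials(plan$trials, params, config, seed = s[2L])

    # practice gate on the randomized block(s)
    rp <- lat[lat$phase == "randomized_practice", ]
    rp_correct <- !is.na(rp$correct) & rp$correct
    gate <- evaluate_practice_gate(rp_correct, config, block = 1L)
    if (gate == "retry") {
      extra_plan <- build_session_plan(config, seed = s[3L])
      extra <- extra_plan$trials[extra_plan$trials$phase ==
                                   "randomized_practice", ]
      extra_seed <- as.integer((as.numeric(s[3L]) + 1000003) %% 2147483646) + 1L
      extra_lat <- sample_latent_trials(extra, params, config,
                                        seed = extra_seed)
      gate <- evaluate_practice_gate(
        !is.na(extra_lat$correct) & extra_lat$correct, config, block = 2L)
    }
    status[i] <- gate

    main <- lat[lat$phase == "main", ]
    traces[[i]] <- render_tilt_traces(main, config,
                                      tremor_sd = params$tremor_sd,
                                      jiggler = params$jiggler,
                                      seed = s[4L])
    lat$subject_id <- params$subject_id
    latent_list[[i]] <- lat
  }

  subjects$practice_status <- status
  names(traces) <- subjects$subject_id
  names(plans) <- subjects$subject_id
  structure(
    list(
      subjects = subjects,
      plans = plans,
      latent = dplyr::bind_rows(latent_list) |>
        dplyr::relocate("subject_id"),
      traces = traces,
      config = config,
      population = population,
      master_seed = as.integer(master_seed)
    ),
    class = "cohort_sim"
  )
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d subjects, master seed %d\n",
              nrow(x$subjects), x$master_seed))
  cat(sprintf("  main-trial presentations: %d\n",
              sum(x$latent$phase == "main")))
  cat(sprintf("  practice status: %s\n",
              paste(names(table(x$subjects$practice_status)),
                    table(x$subjects$practice_status),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
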