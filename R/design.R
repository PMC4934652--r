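#' Session configuration
#'
#' Collects the fixed design constants of a tilt-response rate-discrimination
#' session: a 2 (visual rate: 6 vs 8 Hz) x 2 (auditory rate congruent vs
#' incongruent) main block, a 2 s response deadline enforced by the fish
#' disappearing, a 3 s gap before the next fish spawns, a 17 degree tilt
#' threshold defining a response, and 60 Hz accelerometer sampling. Practice
#' consists of a short guided block followed by one or two randomized blocks
#' of 10 trials gated at 6 correct.
#'
#' @param n_main_trials Number of main-phase trials (default 60).
#' @param trials_per_cell Trials per design cell; must satisfy
#'   `n_main_trials == 4 * trials_per_cell`.
#' @param response_deadline Seconds allowed to respond before the trial is
#'   scored as missed (default 2).
#' @param inter_fish_interval Seconds between a response (or the deadline)
#'   and the next fish's appearance (default 3).
#' @param slow_rate,fast_rate Modulation rates in Hz of the "good" (slow)
#'   and "bad" (fast) species (defaults 6 and 8).
#' @param tilt_threshold Tilt in degrees, relative to the orientation at
#'   fish onset, that defines a response (default 17).
#' @param sample_rate Accelerometer sampling rate in Hz (default 60).
#' @param practice_guided Number of guided practice trials (default 3).
#' @param practice_randomized Number of trials per randomized practice block
#'   (default 10).
#' @param practice_pass_min Minimum correct responses in a randomized block
#'   to pass (default 6).
#' @param practice_max_blocks Maximum randomized practice blocks before the
#'   subject is excluded (default 2).
#'
#' @return An object of class `session_config` (a named list).
#' @examples
#' cfg <- session_config()
#' cfg$n_main_trials
#' @export
session_config <- function(n_main_trials = 60L,
                           trials_per_cell = 15L,
                           response_deadline = 2,
                           inter_fish_interval = 3,
                           slow_rate = 6,
                           fast_rate = 8,
                           tilt_threshold = 17,
                           sample_rate = 60,
                           practice_guided = 3L,
                           practice_randomized = 10L,
                           practice_pass_min = 6L,
                           practice_max_blocks = 2L) {
  cfg <- structure(
    list(
      n_main_trials = as.integer(n_main_trials),
      trials_per_cell = as.integer(trials_per_cell),
      response_deadline = as.numeric(response_deadline),
      inter_fish_interval = as.numeric(inter_fish_interval),
      slow_rate = as.numeric(slow_rate),
      fast_rate = as.numeric(fast_rate),
      tilt_threshold = as.numeric(tilt_threshold),
      sample_rate = as.numeric(sample_rate),
      practice_guided = as.integer(practice_guided),
      practice_randomized = as.integer(practice_randomized),
      practice_pass_min = as.integer(practice_pass_min),
      practice_max_blocks = as.integer(practice_max_blocks)
    ),
    class = "session_config"
  )
  validate_session_config(cfg)
  cfg
}

validate_session_config <- function(cfg) {
  stopifnot(inherits(cfg, "session_config"))
  if (cfg$n_main_trials != 4L * cfg$trials_per_cell) {
    abort(sprintf(
      "`n_main_trials` (%d) must equal 4 * `trials_per_cell` (%d): the 2 x 2 design must be balanced.",
      cfg$n_main_trials, cfg$trials_per_cell
    ), class = "tiltchron_config_error")
  }
  if (!(cfg$slow_rate < cfg$fast_rate)) {
    abort("`slow_rate` must be strictly less than `fast_rate`.",
          class = "tiltchron_config_error")
  }
  durs <- c(cfg$response_deadline, cfg$inter_fish_interval, cfg$sample_rate)
  if (any(durs <= 0)) {
    abort("All durations and rates must be positive.",
          class = "tiltchron_config_error")
  }
  if (cfg$tilt_threshold <= 0) {
    abort("`tilt_threshold` must be positive.", class = "tiltchron_config_error")
  }
  if (cfg$practice_pass_min > cfg$practice_randomized) {
    abort("`practice_pass_min` cannot exceed `practice_randomized`.",
          class = "tiltchron_config_error")
  }
  invisible(cfg)
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  cat(sprintf("  main trials: %d (%d per cell, 2 x 2 design)\n",
              x$n_main_trials, x$trials_per_cell))
  cat(sprintf("  rates: %g / %g Hz; deadline %g s; inter-fish %g s\n",
              x$slow_rate, x$fast_rate, x$response_deadline,
              x$inter_fish_interval))
  cat(sprintf("  tilt threshold %g deg at %g Hz sampling\n",
              x$tilt_threshold, x$sample_rate))
  cat(sprintf("  practice: %d guided + up to %d blocks of %d (pass >= %d)\n",
              x$practice_guided, x$practice_max_blocks,
              x$practice_randomized, x$practice_pass_min))
  invisible(x)
}

species_for_rate <- function(visual_rate, cfg) {
  ifelse(visual_rate == cfg$slow_rate, "good", "bad")
}

#' Build a session's trial schedule
#'
#' Generates the full, seeded trial list for one session: a guided practice
#' block (one congruent trial with sound, one incongruent trial with sound,
#' one no-sound trial), a randomized practice block of
#' `config$practice_randomized` trials drawn uniformly from the four design
#' cells, and a main block with exactly `config$trials_per_cell` trials per
#' (species x congruence) cell in seeded-shuffled order. Entry side
#' alternates by a seeded fair coin.
#'
#' @param config A [session_config()].
#' @param seed Integer seed; the same seed reproduces the identical plan.
#'
#' @return An object of class `session_plan`: a list with elements `config`,
#'   `trials` (a tibble with columns `trial_index`, `phase`, `visual_rate`,
#'   `audio_rate` (`NA` on no-sound trials), `congruent`, `species`,
#'   `entry_side`), and `seed`.
#' @examples
#' plan <- build_session_plan(session_config(), seed = 1)
#' dplyr::count(dplyr::filter(plan$trials, phase == "main"),
#'              species, congruent)
#' @export
build_session_plan <- function(config = session_config(), seed) {
  validate_session_config(config)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  cells <- tidyr::expand_grid(
    visual_rate = c(config$slow_rate, config$fast_rate),
    congruent = c(TRUE, FALSE)
  )
  cells$audio_rate <- ifelse(cells$congruent, cells$visual_rate,
                             ifelse(cells$visual_rate == config$slow_rate,
                                    config$fast_rate, config$slow_rate))

  plan_trials <- local_seed(seed, {
    guided <- tibble::tibble(
      visual_rate = c(config$slow_rate, config$fast_rate,
                      sample(c(config$slow_rate, config$fast_rate), 1L)),
      audio_rate = c(config$slow_rate, config$slow_rate, NA_real_),
      congruent = c(TRUE, FALSE, NA),
      phase = "guided_practice"
    )
    if (config$practice_guided > 3L) {
      extra_idx <- sample.int(nrow(cells), config$practice_guided - 3L,
                              replace = TRUE)
      extra <- cells[extra_idx, ]
      extra$phase <- "guided_practice"
      guided <- dplyr::bind_rows(guided, extra)
    } else if (config$practice_guided < 3L) {
      guided <- guided[seq_len(config$practice_guided), ]
    }

    rand_idx <- sample.int(nrow(cells), config$practice_randomized,
                           replace = TRUE)
    randomized <- cells[rand_idx, ]
    randomized$phase <- "randomized_practice"

    main <- cells[rep(seq_len(nrow(cells)), each = config$trials_per_cell), ]
    main <- main[sample.int(nrow(main)), ]
    main$phase <- "main"

    trials <- dplyr::bind_rows(guided, randomized, main)
    trials$entry_side <- sample(c("left", "right"), nrow(trials),
                                replace = TRUE)
    trials
  })

  trials <- plan_trials |>
    dplyr::mutate(
      trial_index = dplyr::row_number(),
      species = species_for_rate(.data$visual_rate, config)
    ) |>
    dplyr::select("trial_index", "phase", "visual_rate", "audio_rate",
                  "congruent", "species", "entry_side")

  structure(list(config = config, trials = trials, seed = as.integer(seed)),
            class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> seed %d, %d trials (%d main)\n",
              x$seed, nrow(x$trials), sum(x$trials$phase == "main")))
  print(dplyr::count(x$trials, .data$phase))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.session_plan <- function(x, ...) x$trials

#' Gate a randomized practice block
#'
#' Applies the pass rule for a randomized practice block: subjects scoring at
#' least `config$practice_pass_min` correct move on to the main game; those
#' below the threshold receive one additional block; failing again excludes
#' the subject.
#'
#' @param correct_flags Logical vector of per-trial correctness, length
#'   `config$practice_randomized`.
#' @param config A [session_config()].
#' @param block Which randomized block this is (1-based).
#'
#' @return One of `"pass"`, `"retry"`, `"fail"`.
#' @examples
#' evaluate_practice_gate(rep(c(TRUE, FALSE), 5), session_config())
#' @export
evaluate_practice_gate <- function(correct_flags, config = session_config(),
                                   block = 1L) {
  validate_session_config(config)
  if (length(correct_flags) != config$practice_randomized) {
    abort(sprintf(
      "`correct_flags` must have length %d (one per randomized practice trial), got %d.",
      config$practice_randomized, length(correct_flags)
    ), class = "tiltchron_input_error")
  }
  if (anyNA(correct_flags)) {
    abort("`correct_flags` must not contain NA.", class = "tiltchron_input_error")
  }
  if (sum(correct_flags) >= config$practice_pass_min) {
    "pass"
  } else if (block < config$practice_max_blocks) {
    "retry"
  } else {
    "fail"
  }
}

#' Fish spawn timeline
#'
#' Computes when each fish appears, given the per-trial response times. A
#' fish spawns, the player has up to the deadline to respond, and the next
#' fish appears `inter_fish_interval` seconds after the response (or after
#' the deadline when the trial was missed). At-deadline responding therefore
#' yields one fish every `response_deadline + inter_fish_interval` seconds
#' (12 per minute with the defaults).
#'
#' @param plan A [build_session_plan()] result, or an integer trial count.
#' @param response_times Numeric vector of response times in seconds, one per
#'   trial; `NA` marks a missed trial (the full deadline elapses).
#'
#' @return Numeric vector of spawn times in seconds, first element 0.
#' @examples
#' spawn_timeline(3L, c(2, 2, 2))
#' @export
spawn_timeline <- function(plan, response_times) {
  if (inherits(plan, "session_plan")) {
    cfg <- plan$config
    n <- nrow(plan$trials)
  } else {
    cfg <- session_config()
    n <- as.integer(plan)
  }
  if (length(response_times) != n) {
    abort(sprintf("`response_times` must have length %d, got %d.",
                  n, length(response_times)),
          class = "tiltchron_input_error")
  }
  over <- !is.na(response_times) &
    response_times > cfg$response_deadline + 1e-9
  if (any(over)) {
    abort(paste0(
      "Response times exceed the deadline at trial(s) ",
      paste(which(over), collapse = ", "),
      "; mark missed trials as NA."
    ), class = "tiltchron_input_error")
  }
  occupied <- ifelse(is.na(response_times), cfg$response_deadline,
                     response_times)
  gaps <- occupied + cfg$inter_fish_interval
  cumsum(c(0, gaps[-n]))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive reproducible 31-bit sub-seeds from a master seed.
derive_seeds <- function(master_seed, n) {
  local_seed(master_seed, sample.int(2147483646L, n))
}
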