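#' Chronometric decomposition of tilt traces
#'
#' A response is the first 60 Hz accelerometer sample whose tilt, relative to
#' the orientation at fish onset, reaches the threshold (17 degrees) in
#' either direction; its time is the trial's response time. The reaction
#' time is the time of the earliest sample that (a) moves in the same
#' direction as the ultimate threshold-crossing tilt and (b) is not followed,
#' before the crossing, by any reversal — a sample-to-sample tilt change of
#' more than `epsilon` degrees opposite to the response direction. Movement
#' time is the difference: `MT = response_time - reaction_time`.
#'
#' @name chronometry
#' @keywords internal
NULL

# Coerce a trace given as a tibble/data.frame (tilt_deg column) or numeric
# vector into the internal numeric-vector form. Sample 0 is element 1.
as_trace <- function(trace) {
  if (is.data.frame(trace)) {
    if (!"tilt_deg" %in% names(trace)) {
      abort("A trace data frame must have a `tilt_deg` column.",
            class = "tiltchron_input_error")
    }
    if ("sample_index" %in% names(trace)) {
      trace <- trace[order(trace$sample_index), ]
    }
    trace <- trace$tilt_deg
  }
  x <- as.numeric(trace)
  if (length(x) == 0L) {
    abort("Empty tilt trace.", class = "tiltchron_input_error")
  }
  x
}

#' Detect the threshold-crossing response in a tilt trace
#'
#' Finds the first sample at which the absolute tilt reaches `threshold`
#' degrees. Times sit on the sample grid: sample `k` (0-based) maps to
#' `k / sample_rate` seconds, with no sub-sample interpolation.
#'
#' @param trace Numeric vector of signed tilt angles in degrees (sample 0 is
#'   the onset baseline), or a data frame with columns `sample_index`,
#'   `tilt_deg`.
#' @param threshold Response threshold in degrees (default 17; the crossing
#'   is inclusive, `|tilt| >= threshold`).
#' @param sample_rate Sampling rate in Hz (default 60).
#'
#' @return A one-row tibble with columns `missed` (logical),
#'   `response_time` (seconds, `NA` when missed), `response_sample`
#'   (0-based index), and `direction` (`"toward"` for positive tilt,
#'   `"away"` for negative, `"none"` when missed).
#' @examples
#' x <- c(rep(0, 45), seq(17, 30, length.out = 75))
#' detect_response(x)
#' @export
detect_response <- function(trace, threshold = 17, sample_rate = 60) {
  if (threshold <= 0) {
    abort("`threshold` must be positive.", class = "tiltchron_input_error")
  }
  x <- as_trace(trace)
  hit <- which(abs(x) >= threshold)
  if (length(hit) == 0L) {
    return(tibble::tibble(missed = TRUE, response_time = NA_real_,
                          response_sample = NA_integer_, direction = "none"))
  }
  i <- hit[1L]
  tibble::tibble(
    missed = FALSE,
    response_time = (i - 1L) / sample_rate,
    response_sample = i - 1L,
    direction = if (x[i] > 0) "toward" else "away"
  )
}

dir_sign <- function(direction) {
  switch(direction, toward = 1, away = -1,
         abort("`direction` must be \"toward\" or \"away\".",
               class = "tiltchron_input_error"))
}

#' Extract reaction time (movement onset) from a tilt trace
#'
#' Scans the samples up to the threshold crossing for the earliest sample
#' that moves in the response direction and is not followed by any reversal
#' before the crossing. "Moves in the response direction" means, under the
#' default `direction_mode = "velocity"`, that the sample-to-sample tilt
#' increment exceeds `epsilon` degrees toward the eventual response (under
#' `"tilt"`, that the sample's absolute tilt lies more than `epsilon` beyond
#' baseline on the response side). A reversal is an increment of more than
#' `epsilon` degrees opposite to the response direction. The symmetric
#' `epsilon` dead-band is a sensor-noise floor: hand tremor whose
#' sample-to-sample excursions stay below it can neither trigger movement
#' onset nor reset it.
#'
#' Degenerate traces with no qualifying sample (e.g. an instantaneous step to
#' threshold) fall back to `reaction_time = response_time` (movement time 0)
#' with `rt_fallback = TRUE`.
#'
#' @inheritParams detect_response
#' @param response One-row tibble from [detect_response()] (a responded
#'   trial).
#' @param epsilon Reversal/noise tolerance in degrees per sample
#'   (default 0.5).
#' @param direction_mode `"velocity"` (default) or `"tilt"`; see above.
#'
#' @return A one-row tibble with `reaction_time` (seconds),
#'   `reaction_sample` (0-based), and `rt_fallback` (logical).
#' @examples
#' x <- c(rep(0, 13), cumsum(rep(1.5, 12)))  # onset at sample 13
#' r <- detect_response(x)
#' extract_reaction_time(x, r)
#' @export
extract_reaction_time <- function(trace, response, epsilon = 0.5,
                                  direction_mode = c("velocity", "tilt"),
                                  sample_rate = 60) {
  direction_mode <- match.arg(direction_mode)
  x <- as_trace(trace)
  if (isTRUE(response$missed)) {
    abort("Cannot extract a reaction time from a missed trial.",
          class = "tiltchron_input_error")
  }
  s_star <- response$response_sample          # 0-based crossing sample
  d <- dir_sign(response$direction)
  if (s_star == 0L) {
    return(tibble::tibble(reaction_time = response$response_time,
                          reaction_sample = 0L, rt_fallback = TRUE))
  }
  incr <- (x[2:(s_star + 1L)] - x[1:s_star]) * d  # increment at samples 1..s*
  qual <- if (direction_mode == "velocity") {
    incr > epsilon
  } else {
    x[2:(s_star + 1L)] * d > epsilon
  }
  rev_idx <- which(incr < -epsilon)
  last_rev <- if (length(rev_idx)) rev_idx[length(rev_idx)] else 0L
  cand <- which(qual)
  # a reversal disqualifies only onsets it FOLLOWS; the reversal sample
  # itself may qualify (possible in tilt mode only)
  cand <- cand[cand >= last_rev]
  if (length(cand) == 0L) {
    return(tibble::tibble(reaction_time = response$response_time,
                          reaction_sample = as.integer(s_star),
                          rt_fallback = TRUE))
  }
  tibble::tibble(reaction_time = cand[1L] / sample_rate,
                 reaction_sample = as.integer(cand[1L]),
                 rt_fallback = FALSE)
}

#' Brute-force reaction-time oracle
#'
#' Independent reference implementation of the movement-onset criterion:
#' for every sample up to the threshold crossing it literally tests, by
#' exhaustive scan, whether the sample moves in the response direction and
#' whether any later sample up to the crossing reverses by more than
#' `epsilon`, returning the earliest sample passing both tests. Exists to
#' cross-check [extract_reaction_time()]; the two must agree on every trace.
#'
#' @inheritParams extract_reaction_time
#' @return As [extract_reaction_time()].
#' @export
brute_force_rt_oracle <- function(trace, response, epsilon = 0.5,
                                  direction_mode = c("velocity", "tilt"),
                                  sample_rate = 60) {
  direction_mode <- match.arg(direction_mode)
  x <- as_trace(trace)
  if (isTRUE(response$missed)) {
    abort("Cannot extract a reaction time from a missed trial.",
          class = "tiltchron_input_error")
  }
  s_star <- response$response_sample
  d <- dir_sign(response$direction)
  if (s_star > 0L) {
    for (k in 1:s_star) {
      step <- (x[k + 1L] - x[k]) * d
      moving <- if (direction_mode == "velocity") step > epsilon
                else x[k + 1L] * d > epsilon
      if (!moving) next
      reversed <- FALSE
      j <- k + 1L
      while (j <= s_star) {
        if ((x[j + 1L] - x[j]) * d < -epsilon) {
          reversed <- TRUE
          break
        }
        j <- j + 1L
      }
      if (!reversed) {
        return(tibble::tibble(reaction_time = k / sample_rate,
                              reaction_sample = k, rt_fallback = FALSE))
      }
    }
  }
  tibble::tibble(reaction_time = response$response_time,
                 reaction_sample = as.integer(s_star), rt_fallback = TRUE)
}

#' Movement time
#'
#' `MT = response_time - reaction_time`: the motor-execution component left
#' after subtracting the perceptual/decisional onset from the total response
#' latency.
#'
#' @param response_time,reaction_time Times in seconds (vectorized).
#' @return Movement time in seconds (non-negative).
#' @examples
#' movement_time(0.75, 0.55)
#' @export
movement_time <- function(response_time, reaction_time) {
  mt <- response_time - reaction_time
  if (any(mt < -1e-12, na.rm = TRUE)) {
    abort("`reaction_time` exceeds `response_time`.",
          class = "tiltchron_input_error")
  }
  pmax(mt, 0)
}

#' Score a trial's correctness
#'
#' The "bad" (fast, 8 Hz) species is caught by tilting the tablet toward the
#' player; the "good" (slow, 6 Hz) species is released by tilting away. A
#' response is correct when the tilt direction matches the species mapping.
#'
#' @param direction Character vector: `"toward"`, `"away"`, or `"none"`.
#' @param species Character vector: `"good"` or `"bad"`.
#' @return Logical vector; `NA` where `direction` is `"none"`.
#' @examples
#' score_trial(c("toward", "toward", "away"), c("bad", "good", "good"))
#' @export
score_trial <- function(direction, species) {
  if (!all(direction %in% c("toward", "away", "none"))) {
    abort("`direction` must be \"toward\", \"away\", or \"none\".",
          class = "tiltchron_input_error")
  }
  if (!all(species %in% c("good", "bad"))) {
    abort("`species` must be \"good\" or \"bad\".",
          class = "tiltchron_input_error")
  }
  out <- (species == "bad" & direction == "toward") |
    (species == "good" & direction == "away")
  out[direction == "none"] <- NA
  out
}

# Fast internal single-trace decomposition on a bare numeric vector.
# Returns c(missed, response_sample, dir, reaction_sample, fallback);
# -1 where undefined. Mirrors detect_response + extract_reaction_time.
decompose_trace_core <- function(x, threshold, epsilon, velocity_mode = TRUE) {
  hit <- which(abs(x) >= threshold)
  if (length(hit) == 0L) return(c(1, -1, 0, -1, 0))
  i <- hit[1L]
  d <- if (x[i] > 0) 1 else -1
  s_star <- i - 1L
  if (s_star == 0L) return(c(0, 0, d, 0, 1))
  incr <- (x[2:i] - x[1:s_star]) * d
  qual <- if (velocity_mode) incr > epsilon else x[2:i] * d > epsilon
  rev_idx <- which(incr < -epsilon)
  last_rev <- if (length(rev_idx)) rev_idx[length(rev_idx)] else 0L
  cand <- which(qual)
  cand <- cand[cand >= last_rev]
  if (length(cand) == 0L) return(c(0, s_star, d, s_star, 1))
  c(0, s_star, d, cand[1L], 0)
}

#' Decompose all trials of a session
#'
#' Applies response detection, reaction-time extraction, and correctness
#' scoring to every trial of a session, returning one row per trial.
#'
#' @param traces Either a long tibble with columns `trial_index`,
#'   `sample_index`, `tilt_deg`, or a numeric matrix with one column per
#'   trial (rows are samples; column order taken as trial order unless the
#'   matrix has column names coercible to trial indices).
#' @param specs Optional trial specification tibble (needs `trial_index` and
#'   `species`) used to score correctness; when omitted, `correct` is `NA`.
#' @param threshold Response threshold in degrees (default 17).
#' @param epsilon Reversal/noise tolerance in degrees (default 0.5).
#' @param direction_mode `"velocity"` (default) or `"tilt"`.
#' @param sample_rate Sampling rate in Hz (default 60).
#'
#' @return A tibble with one row per trial: `trial_index`, `direction`,
#'   `response_time`, `reaction_time`, `movement_time` (seconds; `NA` when
#'   missed), `missed`, `rt_fallback`, `correct`.
#' @export
decompose_trials <- function(traces, specs = NULL, threshold = 17,
                             epsilon = 0.5,
                             direction_mode = c("velocity", "tilt"),
                             sample_rate = 60) {
  direction_mode <- match.arg(direction_mode)
  velocity_mode <- direction_mode == "velocity"
  mat <- traces_as_matrix(traces)
  n_trials <- ncol(mat)
  out <- matrix(0, nrow = n_trials, ncol = 5L)
  for (j in seq_len(n_trials)) {
    out[j, ] <- decompose_trace_core(mat[, j], threshold, epsilon,
                                     velocity_mode)
  }
  missed <- out[, 1] == 1
  res <- tibble::tibble(
    trial_index = as.integer(colnames(mat) %||% seq_len(n_trials)),
    direction = ifelse(missed, "none",
                       ifelse(out[, 3] > 0, "toward", "away")),
    response_time = ifelse(missed, NA_real_, out[, 2] / sample_rate),
    reaction_time = ifelse(missed, NA_real_, out[, 4] / sample_rate),
    missed = missed,
    rt_fallback = out[, 5] == 1 & !missed
  )
  # MT from integer sample counts: the identity RT + MT = response time is
  # exact on the sample grid
  res$movement_time <- ifelse(missed, NA_real_,
                              (out[, 2] - out[, 4]) / sample_rate)
  if (!is.null(specs)) {
    sp <- specs[match(res$trial_index, specs$trial_index), "species",
                drop = TRUE]
    res$correct <- score_trial(res$direction, sp)
  } else {
    res$correct <- NA
  }
  res[, c("trial_index", "direction", "response_time", "reaction_time",
          "movement_time", "missed", "rt_fallback", "correct")]
}

# Long tibble (trial_index, sample_index, tilt_deg) or matrix -> matrix with
# trial indices as column names.
traces_as_matrix <- function(traces) {
  if (is.matrix(traces)) {
    if (is.null(colnames(traces))) colnames(traces) <- seq_len(ncol(traces))
    return(traces)
  }
  if (!is.data.frame(traces) ||
      !all(c("trial_index", "sample_index", "tilt_deg") %in% names(traces))) {
    abort(paste("`traces` must be a matrix or a data frame with columns",
                "`trial_index`, `sample_index`, `tilt_deg`."),
          class = "tiltchron_input_error")
  }
  traces <- traces[order(traces$trial_index, traces$sample_index), ]
  idx <- unique(traces$trial_index)
  n_per <- table(traces$trial_index)
  if (length(unique(n_per)) != 1L) {
    abort("All trials must have the same number of samples.",
          class = "tiltchron_input_error")
  }
  mat <- matrix(traces$tilt_deg, nrow = n_per[[1]], ncol = length(idx))
  colnames(mat) <- idx
  mat
}

#' Flag subjects whose traces are unusable (continuous jiggling)
#'
#' A trial counts as jittery on either of two signatures of tablet jiggle:
#' (a) more than `sample_frac` of the sample-to-sample tilt changes in the
#' quiet window — from onset up to the extracted movement onset, or the
#' whole trace when the trial has no response — exceed `epsilon` degrees;
#' or (b) the full trace shows at least `flip_min` direction flips among its
#' super-`epsilon` changes. Bounded hand tremor produces neither (its
#' excursions stay below `epsilon`) and a genuine response produces at most
#' one flip (movement plus return), whereas continuous jiggling reverses
#' direction on every oscillation cycle, even on trials where the wobble
#' happens to cross the response threshold almost immediately. A subject is
#' unusable when more than `trial_frac` of their trials are jittery — the
#' signature of a player who continuously jiggled the tablet, making
#' chronometric decomposition impossible; such subjects are excluded from
#' analysis.
#'
#' @inheritParams decompose_trials
#' @param sample_frac Per-trial fraction of super-`epsilon` changes in the
#'   quiet window above which the trial counts as jittery (default 0.25).
#' @param trial_frac Fraction of jittery trials above which the subject is
#'   flagged unusable (default 0.5).
#' @param flip_min Number of direction flips among super-`epsilon` changes
#'   at which a trial counts as jittery (default 3).
#'
#' @return A one-row tibble: `usable` (logical), `prop_jittery_trials`,
#'   `n_trials`.
#' @export
qc_subject <- function(traces, threshold = 17, epsilon = 0.5,
                       sample_frac = 0.25, trial_frac = 0.5,
                       flip_min = 3L) {
  mat <- traces_as_matrix(traces)
  if (ncol(mat) < 1L) {
    abort("Need at least one trace.", class = "tiltchron_input_error")
  }
  jittery <- vapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]
    core <- decompose_trace_core(x, threshold, epsilon)
    # quiet window: samples strictly before movement onset, else whole trace
    upto <- if (core[1] == 1) length(x) else core[4]
    dense <- if (upto >= 2L) {
      mean(abs(diff(x[seq_len(upto)])) > epsilon) > sample_frac
    } else FALSE
    # direction flips among super-epsilon changes over the full trace
    ch <- diff(x)
    v <- sign(ch)[abs(ch) > epsilon]
    flips <- if (length(v) > 1L) sum(diff(v) != 0) else 0L
    dense || flips >= flip_min
  }, logical(1))
  tibble::tibble(usable = mean(jittery) <= trial_frac,
                 prop_jittery_trials = mean(jittery),
                 n_trials = ncol(mat))
}
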