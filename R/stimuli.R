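#' Stimulus configuration
#'
#' Parameters of the audiovisual stimulus: the fish's sinusoidal size
#' modulation, the amplitude-modulated broadband sound, and the jittered swim
#' path. The traverse duration equals the response deadline, since the fish
#' leaves the screen at the deadline. Modulation depths are conventional,
#' clearly suprathreshold values; the original deployment's exact depths and
#' screen geometry are not fixed by the design, so everything here is
#' configurable.
#'
#' @param size_mod_depth Fractional depth of the sinusoidal size modulation
#'   (default 0.15, i.e. +/-15 percent around `base_size`).
#' @param base_size Baseline fish size in pixels (default 100).
#' @param traverse_duration Seconds the fish takes to cross the screen;
#'   equals the response deadline (default 2).
#' @param audio_sample_rate Audio sampling rate in Hz (default 44100).
#' @param am_depth Amplitude-modulation index in (0, 1]; 1 is full
#'   modulation (default 1).
#' @param vertical_jitter_sd Standard deviation in pixels of each random
#'   vertical displacement (default 8).
#' @param jitter_step_interval Seconds between vertical displacements
#'   (default 1/15, i.e. every 4 frames at 60 fps).
#' @param frame_rate Display frame rate in Hz (default 60).
#' @param screen_width,screen_height Screen size in pixels.
#'
#' @return An object of class `stimulus_config` (a named list).
#' @export
stimulus_config <- function(size_mod_depth = 0.15,
                            base_size = 100,
                            traverse_duration = 2,
                            audio_sample_rate = 44100,
                            am_depth = 1,
                            vertical_jitter_sd = 8,
                            jitter_step_interval = 1 / 15,
                            frame_rate = 60,
                            screen_width = 1280,
                            screen_height = 800) {
  if (size_mod_depth < 0 || size_mod_depth >= 1) {
    abort("`size_mod_depth` must be in [0, 1).", class = "tiltchron_config_error")
  }
  if (am_depth < 0 || am_depth > 1) {
    abort("`am_depth` must be in [0, 1].", class = "tiltchron_config_error")
  }
  if (traverse_duration <= 0 || frame_rate <= 0 || audio_sample_rate <= 0) {
    abort("Durations and rates must be positive.",
          class = "tiltchron_config_error")
  }
  structure(
    list(
      size_mod_depth = size_mod_depth, base_size = base_size,
      traverse_duration = traverse_duration,
      audio_sample_rate = audio_sample_rate, am_depth = am_depth,
      vertical_jitter_sd = vertical_jitter_sd,
      jitter_step_interval = jitter_step_interval,
      frame_rate = frame_rate,
      screen_width = screen_width, screen_height = screen_height
    ),
    class = "stimulus_config"
  )
}

#' Sinusoidal size-modulation envelope
#'
#' The fish's size oscillates sinusoidally at the trial's visual rate,
#' starting at the base size (phase zero):
#' `size_k = base_size * (1 + depth * sin(2 pi rate k / frame_rate))`.
#'
#' @param rate Modulation rate in Hz (6 or 8 in the standard design).
#' @param config A [stimulus_config()].
#'
#' @return A tibble with columns `sample_index` (0-based frame), `time`
#'   (seconds), and `size` (pixels).
#' @examples
#' env <- size_envelope(6, stimulus_config())
#' nrow(env)  # 120 frames: 2 s at 60 fps
#' @export
size_envelope <- function(rate, config = stimulus_config()) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    abort("`rate` must be a single positive number.",
          class = "tiltchron_input_error")
  }
  n <- round(config$traverse_duration * config$frame_rate)
  k <- seq_len(n) - 1L
  tibble::tibble(
    sample_index = k,
    time = k / config$frame_rate,
    size = config$base_size *
      (1 + config$size_mod_depth * sin(2 * pi * rate * k / config$frame_rate))
  )
}

#' Amplitude-modulated broadband sound
#'
#' A seeded Gaussian white-noise carrier multiplied by the raised-sine
#' envelope `1 + am_depth * sin(2 pi rate t)` (non-negative for
#' `am_depth <= 1`), then normalized to peak +/-1. The envelope rate is the
#' trial's auditory modulation rate.
#'
#' @inheritParams size_envelope
#' @param seed Integer seed for the noise carrier.
#'
#' @return A tibble with columns `time` (seconds) and `amplitude`
#'   (dimensionless, peak-normalized).
#' @examples
#' snd <- am_broadband_sound(8, stimulus_config(audio_sample_rate = 8000),
#'                           seed = 1)
#' range(snd$amplitude)
#' @export
am_broadband_sound <- function(rate, config = stimulus_config(), seed) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    abort("`rate` must be a single positive number.",
          class = "tiltchron_input_error")
  }
  n <- round(config$traverse_duration * config$audio_sample_rate)
  t <- (seq_len(n) - 1L) / config$audio_sample_rate
  carrier <- local_seed(seed, rnorm(n))
  env <- 1 + config$am_depth * sin(2 * pi * rate * t)
  wave <- carrier * env
  wave <- wave / max(abs(wave))
  tibble::tibble(time = t, amplitude = wave)
}

#' Jittered swim path
#'
#' The fish crosses the screen horizontally at constant speed within the
#' traverse duration, entering from the given side; its vertical position is
#' perturbed by a seeded random walk with Gaussian steps of standard
#' deviation `vertical_jitter_sd` every `jitter_step_interval` seconds,
#' clipped to the screen.
#'
#' @param entry_side `"left"` or `"right"`.
#' @param config A [stimulus_config()].
#' @param seed Integer seed for the vertical jitter.
#'
#' @return A tibble with columns `sample_index`, `time`, `x`, `y` (pixels).
#' @examples
#' path <- swim_path("left", stimulus_config(), seed = 2)
#' all(diff(path$x) > 0)
#' @export
swim_path <- function(entry_side, config = stimulus_config(), seed) {
  entry_side <- match.arg(entry_side, c("left", "right"))
  n <- round(config$traverse_duration * config$frame_rate)
  k <- seq_len(n) - 1L
  x <- config$screen_width * k / (n - 1L)
  if (entry_side == "right") x <- config$screen_width - x
  frames_per_step <- max(1L, round(config$jitter_step_interval *
                                     config$frame_rate))
  n_steps <- ceiling(n / frames_per_step)
  steps <- local_seed(seed, rnorm(n_steps, sd = config$vertical_jitter_sd))
  walk <- cumsum(steps)[ceiling(seq_len(n) / frames_per_step)]
  y <- pmin(pmax(config$screen_height / 2 + walk, 0), config$screen_height)
  tibble::tibble(sample_index = k, time = k / config$frame_rate, x = x, y = y)
}

#' Stimulus bundle for one trial
#'
#' Convenience wrapper generating the visual envelope, audio waveform (when
#' the trial has sound), and swim path for a single trial specification.
#'
#' @param trial One row of a session plan's `trials` tibble.
#' @param config A [stimulus_config()].
#' @param seed Integer seed.
#'
#' @return A list with elements `size_envelope`, `audio` (`NULL` on no-sound
#'   trials), and `path`.
#' @export
stimulus_bundle <- function(trial, config = stimulus_config(), seed) {
  stopifnot(is.data.frame(trial), nrow(trial) == 1L)
  subseeds <- derive_seeds(seed, 2L)
  list(
    size_envelope = size_envelope(trial$visual_rate, config),
    audio = if (is.na(trial$audio_rate)) NULL else
      am_broadband_sound(trial$audio_rate, config, seed = subseeds[1]),
    path = swim_path(trial$entry_side, config, seed = subseeds[2])
  )
}

#' Write a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for the synthesized sounds; amplitudes are
#' clipped to [-1, 1] and quantized to 16 bits.
#'
#' @param amplitude Numeric vector in [-1, 1] (values outside are clipped).
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz.
#'
#' @return `path`, invisibly.
#' @export
write_wav <- function(amplitude, path, sample_rate = 44100) {
  x <- pmin(pmax(amplitude, -1), 1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
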