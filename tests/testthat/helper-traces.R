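# Builders for synthetic tilt traces used across test files.

# A trace that is zero for `quiet` samples, then a linear ramp of
# `step` deg/sample until the end of the window.
ramp_trace <- function(quiet, step, n = 120, direction = 1) {
  x <- c(rep(0, quiet), cumsum(rep(step, n - quiet)))
  direction * x
}

# Random traces exercising the decomposition: a random walk with
# occasional deterministic ramps; roughly half reach threshold.
random_trace <- function(n = 120) {
  kind <- sample(3, 1)
  if (kind == 1) {
    cumsum(rnorm(n, sd = runif(1, 0.2, 4)))
  } else if (kind == 2) {
    # tremor then ramp with a possible mid-course dip
    d <- sample(5:80, 1)
    step <- runif(1, 0.6, 3)
    x <- ramp_trace(d, step, n, direction = sample(c(-1, 1), 1))
    x[2:n] <- x[2:n] + pmin(pmax(rnorm(n - 1, sd = 0.15), -0.24), 0.24)
    if (runif(1) < 0.5) {
      j <- sample(seq(d + 2, n - 2), 1)
      x[j] <- x[j] - sign(x[n]) * runif(1, 0.6, 5)
    }
    x
  } else {
    sin(2 * pi * runif(1, 1, 5) * seq(0, 2, length.out = n)) *
      runif(1, 5, 25) + rnorm(n, sd = 0.5)
  }
}

# Latent tibble for constructing traces directly (main phase, responded).
latent_row <- function(decision_sample, mt_samples, direction = "toward",
                       trial_index = 1L) {
  tibble::tibble(
    trial_index = trial_index,
    phase = "main",
    missed = FALSE,
    correct = TRUE,
    decision_time = decision_sample / 60,
    movement_duration = mt_samples / 60,
    response_direction = direction
  )
}

# Balanced main-phase spec table without a full plan.
main_specs <- function(n_per_cell = 15) {
  df <- tidyr::expand_grid(
    congruent = c(TRUE, FALSE),
    species = c("good", "bad"),
    rep = seq_len(n_per_cell)
  )
  df$trial_index <- seq_len(nrow(df))
  df$phase <- "main"
  df$visual_rate <- ifelse(df$species == "good", 6, 8)
  df[, c("trial_index", "phase", "visual_rate", "congruent", "species")]
}
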