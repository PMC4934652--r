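test_that("latent trials follow the instruction mapping and miss rule", {
  cfg <- session_config()
  specs <- main_specs(5)

  # perfect accuracy: direction follows the species mapping exactly
  perfect <- subject_params(p_correct_congruent = 1,
                            p_correct_incongruent = 1, miss_rate = 0)
  lat <- sample_latent_trials(specs, perfect, cfg, seed = 1)
  expect_true(all(lat$correct))
  expect_equal(lat$response_direction,
               ifelse(lat$species == "bad", "toward", "away"))
  expect_true(all(lat$decision_time + lat$movement_duration <
                    cfg$response_deadline))

  # zero accuracy inverts the mapping
  wrong <- subject_params(p_correct_congruent = 0,
                          p_correct_incongruent = 0, miss_rate = 0)
  lw <- sample_latent_trials(specs, wrong, cfg, seed = 1)
  expect_true(all(!lw$correct))
  expect_equal(lw$response_direction,
               ifelse(lw$species == "bad", "away", "toward"))

  # certain miss: no direction, no times
  missed <- sample_latent_trials(specs, subject_params(miss_rate = 1), cfg,
                                 seed = 2)
  expect_true(all(missed$missed))
  expect_true(all(missed$response_direction == "none"))
  expect_true(all(is.na(missed$decision_time)))

  # determinism
  expect_identical(lat, sample_latent_trials(specs, perfect, cfg, seed = 1))
})

test_that("empirical condition accuracy converges to generating values", {
  cfg <- session_config()
  specs <- tibble::tibble(
    trial_index = 1:10000, phase = "main",
    congruent = rep(c(TRUE, FALSE), 5000),
    species = rep(c("good", "bad"), each = 5000)
  )
  p <- subject_params(p_correct_congruent = 0.85,
                      p_correct_incongruent = 0.70, miss_rate = 0)
  lat <- sample_latent_trials(specs, p, cfg, seed = 33)
  expect_lt(abs(mean(lat$correct[lat$congruent]) - 0.85), 0.01)
  expect_lt(abs(mean(lat$correct[!lat$congruent]) - 0.70), 0.01)

  # mean decision times converge to the per-condition generating means
  expect_lt(abs(mean(lat$decision_time[lat$congruent]) - 0.650), 0.005)
  expect_lt(abs(mean(lat$decision_time[!lat$congruent]) - 0.70921), 0.005)
})

test_that("rendered traces invert the decomposition (constructive cases)", {
  cfg <- session_config()

  # decision at sample 30, MT 10 samples, no tremor:
  # zero through 29, monotone ramp, 17 deg exactly at sample 40
  lat <- latent_row(30, 10)
  tr <- render_tilt_traces(lat, cfg, tremor_sd = 0, seed = 1)
  x <- tr[, 1]
  expect_equal(x[1:30], rep(0, 30))
  expect_true(all(diff(x[30:41]) > 0))
  expect_equal(x[41], 17)
  expect_lt(x[40], 17)

  r <- detect_response(x)
  expect_equal(r$response_sample, 40)
  rt <- extract_reaction_time(x, r)
  expect_equal(rt$reaction_sample, 30)
  expect_equal(movement_time(r$response_time, rt$reaction_time), 10 / 60)

  # missed trial without tremor: an all-zero trace
  miss <- tibble::tibble(trial_index = 1L, phase = "main", missed = TRUE,
                         correct = NA, decision_time = NA_real_,
                         movement_duration = NA_real_,
                         response_direction = "none")
  expect_equal(render_tilt_traces(miss, cfg, tremor_sd = 0, seed = 1)[, 1],
               rep(0, 120))

  # away responses ramp negative
  away <- render_tilt_traces(latent_row(20, 8, "away"), cfg, tremor_sd = 0,
                             seed = 1)[, 1]
  expect_equal(min(away), -75)
  expect_equal(detect_response(away)$direction, "away")

  # latent times outside the window are rejected
  expect_error(render_tilt_traces(latent_row(115, 10), cfg, tremor_sd = 0,
                                  seed = 1),
               class = "tiltchron_input_error")
})

test_that("bounded tremor never perturbs the recovered chronometry", {
  cfg <- session_config()
  set.seed(88)
  for (i in 1:50) {
    d <- sample(5:90, 1)
    m <- sample(0:25, 1)
    lat <- latent_row(d, m, sample(c("toward", "away"), 1))
    x <- render_tilt_traces(lat, cfg, tremor_sd = 0.18,
                            seed = sample.int(1e6, 1))[, 1]
    expect_true(all(abs(diff(x[1:d])) < 0.5))   # tremor below the dead-band
    res <- decompose_trials(matrix(x, ncol = 1), threshold = 17,
                            epsilon = 0.5)
    expect_false(res$missed)
    expect_lte(abs(res$reaction_time * 60 - d), 1)
    expect_lte(abs(res$movement_time * 60 - m), 1)
  }
})

test_that("cohorts are reproducible, sized correctly, and carry ground truth", {
  cohort <- simulate_cohort(n_subjects = 4, master_seed = 11)
  expect_equal(nrow(cohort$subjects), 4)
  expect_equal(sum(cohort$latent$phase == "main"), 4 * 60)
  expect_equal(length(cohort$traces), 4)
  expect_true(all(vapply(cohort$traces, dim, integer(2))[1, ] == 120))

  again <- simulate_cohort(n_subjects = 4, master_seed = 11)
  expect_identical(cohort$latent, again$latent)
  expect_identical(cohort$traces, again$traces)
  other <- simulate_cohort(n_subjects = 4, master_seed = 12)
  expect_false(identical(cohort$latent, other$latent))

  # single subject: one session of 60 main trials
  one <- simulate_cohort(n_subjects = 1, master_seed = 5)
  expect_equal(sum(one$latent$phase == "main"), 60)
  expect_error(simulate_cohort(n_subjects = 0, master_seed = 5))
})

test_that("population draws respect their declared ranges", {
  pars <- sample_subject_params(cohort_population(), n = 500, seed = 21)
  expect_true(all(pars$p_correct_congruent >= 0.05 &
                    pars$p_correct_congruent <= 0.995))
  expect_true(all(pars$age >= 6 & pars$age <= 82))
  expect_true(all(pars$mt_mean > 0))
  expect_lt(abs(mean(pars$p_correct_congruent - pars$p_correct_incongruent) -
                  0.15), 0.02)
  expect_lt(abs(mean(pars$rt_mean_incongruent - pars$rt_mean_congruent) -
                  0.05921), 0.008)
})
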