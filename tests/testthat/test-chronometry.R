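test_that("response detection applies the inclusive first-crossing rule", {
  # +17.0 deg exactly at sample 45 -> response at 0.75 s, toward
  x <- c(rep(0, 45), rep(17, 75))
  r <- detect_response(x)
  expect_false(r$missed)
  expect_equal(r$response_time, 0.75)
  expect_equal(r$direction, "toward")

  # below threshold everywhere -> missed
  m <- detect_response(c(rep(0, 60), rep(16.9, 60)))
  expect_true(m$missed)
  expect_equal(m$direction, "none")

  # first crossing wins even when the other direction crosses later
  y <- rep(0, 120)
  y[31:50] <- seq(-17, -25, length.out = 20)   # -17 deg at sample 30
  y[51:120] <- seq(17, 40, length.out = 70)    # +17 deg from sample 50
  r2 <- detect_response(y)
  expect_equal(r2$response_sample, 30)
  expect_equal(r2$direction, "away")

  expect_error(detect_response(numeric(0)), class = "tiltchron_input_error")
  expect_error(detect_response(x, threshold = 0),
               class = "tiltchron_input_error")
})

test_that("reaction-time extraction follows the onset/no-reversal criterion", {
  # quiet to sample 12, then +1.5 deg/sample reaching 18 at sample 24
  x <- ramp_trace(13, 1.5, n = 40)
  expect_equal(x[25], 18)
  r <- detect_response(x)
  expect_equal(r$response_time, 24 / 60)
  rt <- extract_reaction_time(x, r)
  expect_equal(rt$reaction_time, 13 / 60)
  expect_false(rt$rt_fallback)
  expect_equal(movement_time(r$response_time, rt$reaction_time), 11 / 60)

  # instantaneous step: onset is the crossing itself, RT = response, MT = 0
  step <- c(rep(0, 30), rep(20, 90))
  rs <- detect_response(step)
  rts <- extract_reaction_time(step, rs)
  expect_equal(rts$reaction_time, 0.5)
  expect_equal(movement_time(rs$response_time, rts$reaction_time), 0)

  # pathological trace with no qualifying onset: sub-epsilon creep reaches
  # threshold without any single super-epsilon step -> fallback, flagged
  creep <- seq(0, -17, length.out = 120)       # -0.143 deg/sample creep
  rc <- detect_response(creep)
  rtc <- extract_reaction_time(creep, rc)
  expect_true(rtc$rt_fallback)
  expect_equal(rtc$reaction_time, rc$response_time)

  # a super-epsilon dip resets the onset: ramp to 10 by sample 20,
  # dip to 8 at 21, re-ramp crossing 17 at sample 30
  z <- c(seq(0, 10, by = 0.5), 8, seq(9, 17, by = 1), rep(18, 88))
  rz <- detect_response(z)
  expect_equal(rz$response_sample, 30)
  rtz <- extract_reaction_time(z, rz)
  expect_equal(rtz$reaction_time, 22 / 60)
})

test_that("movement time is the response/reaction difference and non-negative", {
  expect_equal(movement_time(0.75, 0.55), 0.2)
  expect_equal(movement_time(0.5, 0.5), 0)
  expect_error(movement_time(0.5, 0.6), class = "tiltchron_input_error")
})

test_that("correctness scoring matches the species-direction mapping", {
  # exhaustive 2 x 2 table: bad/toward and good/away are correct
  grid <- expand.grid(direction = c("toward", "away"),
                      species = c("good", "bad"),
                      stringsAsFactors = FALSE)
  got <- score_trial(grid$direction, grid$species)
  expect_equal(got, c(FALSE, TRUE, TRUE, FALSE))
  expect_true(is.na(score_trial("none", "good")))
  expect_error(score_trial("up", "good"), class = "tiltchron_input_error")
})

test_that("optimized extraction equals the brute-force oracle on random traces", {
  set.seed(202)
  n_checked <- 0
  for (i in 1:1500) {
    x <- random_trace()
    r <- detect_response(x)
    if (r$missed) next
    a <- extract_reaction_time(x, r)
    b <- brute_force_rt_oracle(x, r)
    expect_identical(a$reaction_sample, b$reaction_sample)
    expect_identical(a$rt_fallback, b$rt_fallback)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 500)

  # agreement holds in absolute-tilt direction mode too
  set.seed(203)
  for (i in 1:300) {
    x <- random_trace()
    r <- detect_response(x)
    if (r$missed) next
    expect_identical(
      extract_reaction_time(x, r, direction_mode = "tilt")$reaction_sample,
      brute_force_rt_oracle(x, r, direction_mode = "tilt")$reaction_sample)
  }
})

test_that("raising the threshold never hastens a response or revives a miss", {
  set.seed(301)
  for (i in 1:300) {
    x <- random_trace()
    lo <- detect_response(x, threshold = 17)
    hi <- detect_response(x, threshold = 22)
    if (lo$missed) {
      expect_true(hi$missed)
    } else if (!hi$missed) {
      expect_gte(hi$response_time, lo$response_time)
    }
  }
})

test_that("trial-table decomposition preserves the chronometric identity", {
  set.seed(77)
  mat <- sapply(1:80, function(i) random_trace())
  specs <- tibble::tibble(trial_index = 1:80, phase = "main",
                          species = sample(c("good", "bad"), 80,
                                           replace = TRUE))
  res <- decompose_trials(mat, specs)
  expect_equal(nrow(res), 80)
  responded <- res[!res$missed, ]
  expect_identical(round(responded$reaction_time * 60) +
                     round(responded$movement_time * 60),
                   round(responded$response_time * 60))
  # all times on the 60 Hz grid
  expect_true(all(abs(responded$response_time * 60 -
                        round(responded$response_time * 60)) < 1e-9))
  expect_true(all(abs(responded$reaction_time * 60 -
                        round(responded$reaction_time * 60)) < 1e-9))
  expect_true(all(is.na(res$response_time[res$missed])))
  expect_equal(res$correct[!res$missed],
               score_trial(responded$direction,
                           specs$species[!res$missed]))
})

test_that("QC flags jigglers and spares calm players", {
  cfg <- session_config()
  lat <- dplyr::bind_rows(lapply(1:20, function(i) {
    latent_row(sample(20:80, 1), sample(5:15, 1),
               sample(c("toward", "away"), 1), trial_index = i)
  }))
  calm <- render_tilt_traces(lat, cfg, tremor_sd = 0.15, seed = 8)
  expect_true(qc_subject(calm)$usable)

  wobble <- render_tilt_traces(lat, cfg, tremor_sd = 0.15, jiggler = TRUE,
                               seed = 8)
  q <- qc_subject(wobble)
  expect_false(q$usable)
  expect_gt(q$prop_jittery_trials, 0.5)
})
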