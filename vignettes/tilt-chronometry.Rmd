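---
title: "Tilt-response chronometry and audiovisual congruency analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tilt-response chronometry and audiovisual congruency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiltchron)
```

## The task and the measurement problem

`tiltchron` implements the analysis pipeline for a speeded two-alternative
forced-choice experiment in which a fish-like target crosses a tablet screen
while oscillating sinusoidally in size at either 6 Hz (the "good," slow
species) or 8 Hz (the "bad," fast species). A concurrent, task-irrelevant
broadband sound is amplitude modulated at 6 or 8 Hz, so the auditory rate is
either congruent or incongruent with the visual rate. The player classifies
each target within 2 s by tilting the tablet: toward themselves to catch a
fast target, away to release a slow one. The tablet's accelerometer samples
tilt at 60 Hz, reset to zero at each target's onset, and a tilt of 17
degrees or more in either direction registers the response. Three seconds
after a response (or the lapsed deadline) the next target appears, so
at-deadline play presents 12 targets per minute and a 60-trial session
lasts at most five minutes.

The scientific quantity of interest is the *congruency effect*: how much
more accurately and faster players respond when the irrelevant sound shares
the visual rate. Because total response latency confounds perceptual
processing with motor execution, the pipeline decomposes each trial's
response time into a *reaction time* (RT, decision onset) and a *movement
time* (MT, motor execution), and all latency inference is done on RT.

## The chronometric decomposition

For each trial the algorithm works offline over the stored 60 Hz samples:

1. **Response detection.** The response time is the time of the first
   sample whose absolute tilt reaches the 17 degree threshold (inclusive);
   its sign gives the response direction.
2. **Movement onset.** Scanning the samples up to that crossing, the
   reaction time is the earliest sample that moves in the response
   direction and is not followed, before the crossing, by any *reversal* —
   a sample-to-sample tilt change of more than `epsilon` degrees opposite
   to the response direction.
3. **Movement time.** `MT = response time − reaction time`, so
   `RT + MT = response time` holds exactly on every responded trial.

All times live on the 60 Hz sample grid (`k / 60` s, no sub-sample
interpolation): the sampling rate is an irreducible resolution limit, and
pretending to finer precision would be spurious.

### Numerical choices

* **The noise tolerance `epsilon` (default 0.5 degrees per sample)** is
  applied symmetrically: a sample counts as *moving in the response
  direction* only when its increment exceeds `epsilon`, and as a *reversal*
  only when its increment exceeds `epsilon` the other way. Changes inside
  the dead band count as neither. The symmetric band is what makes the
  decomposition robust to hand tremor: tremor whose sample-to-sample
  excursions stay below `epsilon` can neither trigger a movement onset nor
  reset one. Under a strict sign rule (any positive increment counts as
  movement) every pre-decision tremor up-tick would be adopted as the
  onset, because sub-tolerance tremor can never produce a disqualifying
  reversal; reaction times would then be biased early by the full tremor
  duration rather than by at most one sample.
* **Direction of a sample** is judged by its velocity (increment sign) by
  default, reading "moves in the same direction" as a statement about
  motion. An alternative reading — the sample's absolute tilt lies on the
  response side of baseline — is available as `direction_mode = "tilt"`;
  whichever mode is chosen, the brute-force oracle uses the identical rule,
  and the two implementations are verified equal on randomized traces.
* **Degenerate traces** (e.g. an instantaneous step to threshold, or
  sub-tolerance creep that reaches threshold without any single
  super-tolerance step) fall back to `reaction time = response time`
  (MT = 0) and are flagged via `rt_fallback` rather than raising an error.
* **A reversal disqualifies only onsets it follows.** In tilt mode a sample
  can simultaneously be a reversal (by velocity) and lie in the response
  direction (by tilt); such a sample may itself be the onset.

### Resolvability limit

The renderer draws the movement as a linear ramp from baseline to
threshold. Its per-sample velocity is `17 / (m + 1)` degrees for an
`m`-sample movement, so ramps longer than about 33 samples (MT above
roughly 0.55 s) sink below the 0.5 degree dead band and are no longer
detectable as movement — the decomposition then falls back to MT = 0. This
is a statement about signal, not a bug: a movement slower than the sensor
noise floor is indistinguishable from drift. The acceptance grid therefore
covers MT from 0 to 32 samples (0–533 ms), several times the plausible
motor range (the cohort default is 170 ms).

## Quality control

One player in the original deployment continuously jiggled the tablet,
making decomposition impossible; the pipeline reproduces that exclusion
rule. A trial counts as
jittery on either of two signatures:

* more than 25% of the sample-to-sample changes in the quiet window (from
  onset up to the extracted movement onset, or the whole trace on missed
  trials) exceed `epsilon`; or
* the full trace contains three or more direction flips among its
  super-`epsilon` changes.

The second signature matters for wobble violent enough to cross the
response threshold within a few samples, which leaves no quiet window to
inspect: bounded tremor produces no super-`epsilon` change at all, and a
genuine movement-plus-return produces at most one flip, whereas continuous
jiggling reverses direction on every oscillation cycle. A subject with more
than 50% jittery trials is excluded from all cohort statistics.

## The synthetic-data generator

No raw data from the original deployment are public, so the package ships a
first-class generator whose defaults state the cohort the analysis targets:

| Parameter | Default | Source / rationale |
|---|---|---|
| accuracy, congruent / incongruent | 0.80 / 0.65 | cohort effect 0.15 |
| between-subject sd of the accuracy effect | 0.12 | chosen so the cohort t statistic is of the reported order (~6.9) |
| mean RT, congruent | 650 ms | free choice; per-condition levels were not reported |
| RT congruency effect | 59.21 ms | reported cohort mean difference |
| between-subject sd of the RT effect | 50 ms | cohort t of the reported order (~6.0) |
| RT distribution | lognormal, log-sd 0.25 | standard positively skewed chronometric choice |
| MT | normal(170, 40) ms, truncated at 0 | reported MT means ~163–176 ms; no congruence effect |
| tremor sd | uniform 0.05–0.20 degrees | sub-threshold hand tremor, bounded below `epsilon` |
| miss rate | 0.008 | 28 deadline misses in 3,600 presentations |
| jiggler prevalence | 1/60 | one excluded subject in a 60-player cohort |
| ages | uniform 6–82 years | reported age range; effects age-independent by default |

Reaction times are lognormal and movement times truncated normal because
only means were reported; these are conventional shapes, and all recovery
tests target *injected* parameters, not the original raw data. Correctness
is Bernoulli per trial with the congruence-appropriate probability; the
response direction follows the species mapping when correct and inverts it
otherwise. No-sound practice trials use the congruent accuracy, since no
auditory interference is present. Latent times are redrawn until the
threshold crossing fits inside the 2 s window on the 60 Hz grid, so
simulated responded trials always beat the deadline, and practice blocks
are gated exactly as in the session design (a second sub-threshold
randomized block excludes the subject — the original report does not say
what happened after a second failure; exclusion is this package's choice).

What a green test does and does not establish: the generator is
*descriptive*. It matches the trial schedule, the trace morphology the
decomposition rule inverts (quiet tremor, a monotone ramp through
threshold), and the reported summary statistics; it does not model decision
formation (no drift-diffusion), motor kinematics (real movements are not
linear ramps), sensor quirks, or any age structure in the effects.
Parameter-recovery results therefore validate the *pipeline* — that the
decomposition and statistics recover what was injected — not the original
behavioral claims, which would require the original data.

## Cohort statistics

Per subject, main-phase trials are aggregated into the two congruence
categories (ignoring the specific visual rate, which leaves only 15 trials
per design cell — too few for stable per-cell estimates): proportion
correct over responded trials, and mean RT and MT over correct responded
trials only. Missed trials are excluded from both the accuracy denominator
and the latency means and counted separately. The accuracy effect is
congruent minus incongruent; the RT effect is incongruent minus congruent,
so both are positive when congruence helps.

Cohort inference uses one-sample, two-sided t tests on the per-subject
effects (df = n − 1). Error bars for condition means are within-subject
SEMs: Cousineau subject-centering with Morey's `J/(J−1)` bias correction
(J = 2) — the concept was named in the source design but not the formula,
so this standard construction is the package's choice. The speed–accuracy
relation is a Pearson correlation between the two effect measures with a
Fisher-z 95% CI, plus a median-split quadrant count as a distributional
diagnostic. Age trends are plain per-measure OLS regressions of each effect
on age (the original regression specification was unstated; no weighting,
no joint model).

## A worked run

```{r}
cohort <- simulate_cohort(n_subjects = 12, master_seed = 7)
fit <- analyze_cohort(cohort)
fit$stats
```

```{r, fig.width = 6, fig.height = 3}
plot_congruency_effects(fit$summaries)
```

Ground truth is kept separate from the observable traces, so recovery can
be audited directly:

```{r}
rec <- recovery_table(cohort, fit$results)
ok <- rec[!rec$missed_true & !rec$missed_est, ]
summary(abs(ok$rt_error) * 60)   # RT error in samples
```

## Known limitations

* The stimulus module synthesizes envelopes, AM noise, and jittered paths
  for completeness and testing; actual screen geometry, fish speed, and
  modulation depths of the original deployment are unreported, so they are
  configuration with conventional defaults and nothing downstream depends
  on them.
* The reported headline statistics of the original 60-player cohort are
  calibration targets for the generator defaults, not reproducible
  quantities: the original raw records are not public.
* Movement times above ~0.55 s are unresolvable under the linear-ramp model
  and the default dead band (see above).
* The practice gate, entry-side schedule, and guided-practice composition
  involve design choices where the source was silent; each is seeded,
  configurable, and recorded in the session plan for replay.
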