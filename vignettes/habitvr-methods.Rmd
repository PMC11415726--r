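---
title: "Models and methods behind habitvr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind habitvr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`habitvr` is a headless, seedable re-implementation of a home-based bimanual
upper-extremity rehabilitation game (of the HABIT-VR family) together with
the complete measurement chain a single-case home study of such a game
needs: task-performance metrics, adherence and dose accounting, controller
actigraphy with intensity classification, and three-phase single-case
statistics. This vignette explains the models, their parameters and units,
the design decisions taken where the underlying game and study protocol
leave details open, and what the synthetic data can and cannot show.

## The game model

The player fires rockets at robot targets. Each launch is one *attempt*; a
robot contact scores one point; a session ends automatically after 30
minutes (`session_cap_s = 1800`). Three mechanics shape play:

* **Adaptive difficulty.** The game has 5 levels, every session starting at
  level 1. Level $\ell$ sets the target speed to
  $v_0 (1 + 0.25)^{\ell - 1}$ and the target size to
  $s_0 (1 - 0.10)^{\ell - 1}$. A rolling window of recent robot-directed
  launches yields a success rate $r$; the level steps up when
  $r > 0.60$, down when $r < 0.30$, clamped to $[1, 5]$. The published
  design specifies "the last set of attempts within a specific time frame"
  without numbers; here the window is the most recent **20** robot launches
  no older than **60 s**, evaluated after every launch once **5** launches
  have accumulated, and cleared on every level change so a new level is
  judged only on evidence gathered there. All three constants are
  configurable (`eval_window`, `eval_window_span_s`, `eval_min_attempts`).
* **Target score and boss battle.** The game perpetually tracks the high
  score and sets the target score 5% above it (rounded half-up, minimum
  increment 1, so the target is always strictly above the high score yet
  beatable). Reaching the target unlocks the boss: a large target requiring
  **7** hits, each within **3 s** of the previous hit; a longer gap restarts
  the chain. On completion the high score and target refresh immediately and
  the session continues; whether the boss can be unlocked again in the same
  session is a flag (`allow_boss_repeat`, default on), since the underlying
  design does not say.
* **Power-ups.** Four effects — bigger rockets, target freeze, rapid fire,
  triple rockets — spawn as stationary orbs (Poisson, mean 1/min, half the
  robot size). Their magnitudes are not quantified in the published design;
  the defaults are: size factor 1.5 for 15 s, speed 0 for 5 s, half the
  minimum inter-launch interval for 10 s, and 3 rockets per launch for 10 s
  (a launch hits if any of the three would). Power-up shots are excluded
  from the difficulty controller's window (a stationary orb probes a
  different skill than a moving robot) but count as attempts in accuracy,
  and score no points.

## The virtual player

The real child's motor behaviour is unobservable, so all player constants
are free parameters with documented defaults (`player_params()`); the
defaults are a calibration, not a claim about any child.

* **Hit model.** $p = \sigma(a \cdot \text{skill} - b \cdot v / s)$ with
  skill scale $a = 2$ and demand scale $b = 0.4$; $v/s$ is the
  speed-to-size demand ratio of the current target. $p$ is strictly
  decreasing in speed and increasing in size and skill.
* **Two-stage learning.** Over cumulative practice hours $t$,
  $\text{skill}(t) = s_0 + A\,(1 - e^{-r_f \min(t, t_f)}) +
  B\,(1 - e^{-r_s \max(0, t - t_f)})$ with $s_0 = 1$, $A = 0.45$,
  $r_f = 1.2\,\text{h}^{-1}$, $t_f = 2$ h, $B = 0.35$,
  $r_s = 0.15\,\text{h}^{-1}$: a sharp early rise followed by slow
  incremental gains, the canonical fast/slow motor-learning pattern. Note
  the fast stage stops accruing at $t_f$, so the exact skill limit is
  $s_0 + A(1 - e^{-r_f t_f}) + B \approx 1.76$, which is what
  `learning_asymptote()` reports.
* **Attempt timing.** Inter-launch intervals are a minimum interval
  (0.8 s) plus an exponential component; the implied rate grows with skill
  (`12.5 + 12.5 * skill` launches/min, i.e. 25/min at starting skill and
  ~34/min when fully learned). During the boss battle intervals halve
  (rapid chained firing is the boss's demand). A linear within-session
  fatigue decrement is available but off by default — it is motivated by
  the qualitative boredom/intensity observation in home use, not by any
  quantified value.
* **Calibration.** With these defaults a novice's 30-minute session at
  level-capped difficulty produces accuracy in the mid-60% range, rising to
  the high-80% range after ~14 practice hours, with firing rates moving
  from ~25 to ~34 shots/min — the operating regime of the home study this
  package models (baseline accuracy ~67%, post ~88%). The calibration was
  fixed once, before the acceptance checks were frozen.
* **High-score priming.** A perpetual high-score tracker starting at zero
  would make the very first session degenerate (target score 1, immediate
  boss). The study protocol therefore carries `initial_high_score`
  (default 400), standing in for the familiarisation play that typically
  precedes a home deployment.

## Synthetic accelerometry

Each session yields two 3-axis series at 120 Hz (`generate_accel()`): a
constant gravity vector plus white sensor noise (SD 0.02 g), with a
damped-oscillation burst (peak 1.0 g, 1.5 Hz, $\tau = 0.25$ s, 0.6 s) at
every attempt. The task is bimanual — one hand holds, the other touches —
so both hands receive a burst per attempt, the nondominant scaled by
`hand_asymmetry` (default 0.45). Burst envelopes are deterministic and only
their directions are random, so the nondominant/dominant burst-energy ratio
equals the asymmetry factor exactly up to noise. The burst frequency sits
inside the activity-counts band on purpose: movement energy should register
as counts.

What this generator does *not* emulate: posture and orientation changes
(gravity is fixed), smooth pursuit movement between attempts, tremor or
spasticity signatures, or any within-burst structure beyond a damped tone.
Passing tests therefore show that the measurement chain is faithful to its
own definitions and monotone in movement energy — not that it reproduces
any particular child's accelerometry.

## Activity counts and intensity classes

The counts pipeline (`compute_counts()`) re-implements the function of
commercial count-processing software as an open, fully parameterised chain:
per axis, remove the mean, band-pass 0.25–2.5 Hz (3rd-order zero-phase
Butterworth; this also removes gravity/DC), rectify, subtract a 0.068 g
dead-band (floored at zero), clip at 2.13 g, quantise by 1/128 g, and sum
per 60 s epoch. Every constant is exposed in `counts_config()`. Whether a
proprietary filter matches this chain exactly is unknowable from the
outside; equivalence is not claimed.

Raw series are recorded at 120 Hz and down-sampled to 30 Hz first
(`downsample_accel()`: zero-phase 4th-order Butterworth at
$0.45 \times$ the target rate, then decimation).

Intensity classes use counts-per-minute cutoffs (`cutoff_set()`), default
Evenson youth values (sedentary $\le$ 100, light $\le$ 2295, moderate
$\le$ 4011 cpm) — shipped as overridable configuration since the
convention, not this package, defines them. Intervals are closed above.
The conventional cutoff definition uses a single ("vertical") axis, here z;
a vector-magnitude mode exists for sensitivity analysis. Epoch length and
axis choice are configurable because the underlying study does not state
which the commercial software used.

## Adherence and dose

Days classify by total minutes played: full $\ge$ 60, half $\ge$ 30,
none otherwise — thresholds rather than session counts, so irregular logs
remain classifiable. The default synthetic 22-day pattern has 11 full,
5 half and 6 skipped days (skips early, halves in the middle, matching the
reported adherence narrative); note 11 + 5/2 = 13.5 h of exact dose, while
the narrative rounds to 14 h — `dose_accounting()` reports the exact
arithmetic and leaves the rounding to the reader.

## Single-case statistics

Metrics are analysed over three phases (baseline, intervention, post).
`phase_summary()` defaults to the *population* SD (divide by $n$), the
convention that reproduces the printed COPM summary values; the sample SD
is available. `cohens_d()` offers the pooled-SD formula (sample variances,
$n_a + n_b - 2$ denominator) and a baseline-SD mode, because single-case
reports are often ambiguous about the denominator; with a single post
value the pooled formula degenerates gracefully to the baseline spread.
Bands on $|d|$: $<0.2$ negligible, $<0.5$ small, $<0.8$ medium, else
large. Per-phase trends are ordinary least squares over session index.
`copm_analyze()` computes per-goal deltas and counts goals at or above the
2-point minimal clinically important difference. Randomisation tests,
Tau-U and multilevel single-case models are out of scope.

## Numerical choices and degenerate inputs

* Event timestamps are canonicalised to 1 ms so logs round-trip exactly
  through CSV.
* Target-score rounding is half-up (39.9 → 40) with a strict minimum
  increment of 1.
* All parsers reject rather than coerce: unknown config keys, out-of-range
  COPM scores, malformed headers and non-monotone timestamps raise errors
  naming the offending line.
* `cohens_d()` with zero spread in its denominator raises an
  undefined-effect error instead of returning infinity; `phase_trend()`
  requires $n \ge 2$; a single-epoch intensity summary is exact.
* Learning-curve fitting works on the logit scale, where the hit model
  makes log-odds affine in skill at a fixed level, so the skill curve's
  rates transfer to the accuracy curve; `minpack.lm::nlsLM` with
  non-negative rate bounds keeps the fit stable.

## Problem sizes

The test suite runs most behavioural checks on 2-minute sessions; the
closed-loop controller property uses 20 full 30-minute stationary-player
sessions, and the learning-recovery and phase-ordering checks use 20
complete simulated studies (31 sessions each, event logs only), fitting the
learning curve to the seed-averaged accuracy series. These sizes give
stable statistics while keeping a full check run in a few minutes on one
CPU; accelerometry is generated per session on demand rather than stored.

## Known limitations

* The virtual player is a calibration device, not a model of cerebral
  palsy: no spasticity, mirror movements, fatigue dynamics (by default) or
  engagement effects.
* The spatial game is abstracted to a (speed, size) demand ratio; no
  collision geometry or 3D motion model exists.
* Counts are an open re-implementation; absolute cpm values are comparable
  within this package, not across devices or proprietary pipelines.
* Effect sizes from a 3-point baseline against a single post observation
  are fragile by construction; the package computes them because the study
  design asks for them, and offers both denominator conventions.

```{r}
library(habitvr)
ds <- simulate_study(seed = 1)
sm <- study_metrics(ds)
aggregate(accuracy ~ phase, sm, mean)
```
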