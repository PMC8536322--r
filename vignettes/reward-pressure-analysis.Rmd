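---
title: "Analysing choking under pressure in cued-reward reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing choking under pressure in cued-reward reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachpressure)
```

## The problem

In cued-reward reaching experiments, a subject (typically a rhesus monkey)
holds a cursor in a central start target, is shown a cue announcing the
reward at stake — from a small sip of water up to a rare, very large
"Jackpot" — and after a variable delay must reach quickly and accurately to
a peripheral target and hold there. The striking empirical finding this
package is built around is that success does not grow monotonically with
the stake: it rises from small to large rewards and then *falls* for the
rare Jackpot. That inverted-U is the behavioral signature of choking under
pressure.

`reachpressure` packages the full trial-level analysis that supports that
conclusion: kinematic decomposition of each reach, an exhaustive
trial-outcome taxonomy, and the reward-condition statistical battery —
together with a synthetic session generator so that every step is testable
end to end without experimental data.

## Trial model and outcome taxonomy

A trial unfolds in three epochs. During the **delay** epoch the cursor must
stay inside the start target (radius `center_radius`, default 5 mm) until
the go cue, which occurs `cue_onset_delay` (200 ms) plus a uniform draw
from `delay_range` after trial start. During the **reach** epoch the cursor
must come to rest inside the reach target (radius `target_radius`, 9 mm,
centered `target_distance` = 80 mm away) within `reach_timeout` (1000 ms).
During the **target-hold** epoch it must remain there for `hold_duration`
(400 ms).

Each trial receives exactly one label, assigned by the first rule violated
in temporal order:

1. `false_start` — speed exceeds 50 mm/s before the go cue;
2. `delay_drift` — the cursor exits the start target before the go cue at
   sub-reach speed;
3. `success` — a qualifying stop inside the target followed by a complete
   hold;
4. `overshoot` — the cursor passes through or beyond the target without a
   qualifying stop;
5. `undershoot` — the reach times out short of the target or mid-flight;
6. `target_hold_drift` — the cursor stops in the target but leaves before
   the hold elapses;
7. `other` — residual cases (flagged).

A *qualifying stop* is a sample inside the target with speed below 10% of
the trial's peak that stays inside for at least 50 ms. The dwell
requirement is what separates a genuine stop from a slow transit through
the target on the way past it; without it, decelerating overshoots that
graze the far edge of the target would masquerade as entries. The 50 mm/s
initiation threshold separates launched reaches (false starts) from slow
positional drifts; both thresholds are configurable and the defaults are
declared approximations, since experimental control software typically
applies its own (unpublished) debounce rules.

`epoch_of_failure()` maps the labels onto epochs (false starts and delay
drifts → delay; under/overshoots → reach; hold drifts → target-hold),
which is how the per-epoch choking analyses are organised.

## Kinematic statistics

Reaches decompose into a *ballistic* phase — the initial, visually
uncorrected launch up to peak speed — and a *homing* phase, the corrective
final approach. Two bespoke statistics quantify them.

**Ballistic endpoint prediction.** The vector velocity from the go cue to
the time of peak speed is reflected about the peak time (the peak sample
used once) and the resulting time-symmetric profile is integrated
trapezoidally; the prediction is the go-cue position plus that
displacement. For a movement whose velocity profile really is symmetric
(minimum-jerk, for instance) the prediction equals the realised endpoint;
for a reach that is later corrected under visual feedback it estimates
where the launch alone would have landed. Two numerical facts are worth
stating. First, the trapezoidal integral of the mirrored profile is
algebraically exactly twice the trapezoidal integral up to the peak, so
the "doubling identity" — mirrored displacement = 2 × displacement at peak
— holds to machine precision against a position-difference reference on
noise-free trajectories; with per-sample sensor tremor the
position-difference reference itself is contaminated at the
tremor-over-amplitude scale, which is why the identity sweep in the test
suite renders tremor-free. Second, ties in peak speed are broken by the
earliest sample, and a peak at the first post-go sample is degenerate: the
function returns the go-cue position and flags the trial.

**Homing time.** The time from the cursor first covering
`homing_start_fraction` (default 2/3) of the distance to the target to its
first subsequent arrival within `homing_proximity` (1 mm) of the target.
Progress is measured by projection onto the start-to-target axis (a
path-length option exists), and proximity is referred to the target
*acceptance boundary* — distance to target center ≤ `target_radius` + 1 mm
— because the buffer exists to let near-miss undershoots complete the
measurement; a center-referenced switch is provided. The search window
extends `homing_buffer` (150 ms) past the reach timeout for the same
reason. Either event failing to occur yields an undefined, flagged value;
undefined values are excluded from medians and tallied.

One property deserves emphasis because it is easy to get backwards: with
these definitions, raising the start fraction moves the start event later
while the end event cannot move earlier than it, so homing time is
*non-increasing* in the start fraction (and in the proximity). What is
robust across start fractions of 1/2, 2/3 and 3/4 is the *ordering of
conditions* — reward conditions with longer final approaches keep longer
median homing times whichever fraction is used — and that is the
robustness property the test suite asserts.

Reaction time is offered under two operationalizations (first exit from
the start target, or first crossing of 10% of trial peak speed), since the
quantity is not uniquely defined for movements that begin before the go
cue; pre-go initiations yield negative, flagged values. Speed profiles are
central differences (one-sided at the edges) smoothed by a 25 ms moving
average; the smoother is deliberately minimal-assumption, is used only to
locate peaks, and all documented properties hold at the default window.

## The statistical battery

Per reward cue, `condition_stats()` reports the success rate with a
bootstrap standard error: trials are resampled with replacement (same n)
10,000 times and the SE is the SD of the resampled rates — at large
`n_boot` this converges to the analytic binomial SE `sqrt(p(1-p)/n)`, which
the tests check at 10% relative tolerance. Pairwise success-rate
comparisons use a two-sided two-proportion z-test with pooled variance,
reported in percentage points; Welch's unequal-variance t covers mean
comparisons (peak speed, ballistic distance) and the Mann-Whitney U test
with tie correction covers heavy-tailed time metrics, summarised by
medians. No multiple-testing correction is applied: per-comparison p
values with star levels 0.05/0.01/0.001 mirror how such results are
conventionally reported in this literature.

`choking_profile()` assembles the per-cue stats, the Small–Large and
Large–Jackpot comparisons (plus any configured control pairs such as
Rare-Large or Common-Jackpot), and a choking flag: Large rate above
Jackpot rate with p < 0.05. `failure_mode_decomposition()` expresses a
success-rate change between two cues as per-failure-mode contributions in
percentage points; because outcome proportions sum to one within each cue,
the contributions sum *exactly* to the negated success delta, a
conservation law the tests assert at 1e-9.

`session_choking_counts()` counts a session as choking when its Jackpot
rate is below its Large rate — a point decrement, not a significance
criterion, because Jackpots are 5% of trials and per-session Jackpot
counts are far too small for per-session tests to be powered; ties do not
count, and a significance-based count is reported alongside for
transparency. `choice_preference()` summarises the two-target choice task
(proportion of trials choosing the higher-magnitude cue per pair; side
bias on equal pairs), the standard check that subjects actually value the
cues.

## The synthetic generator

`generate_session()` emulates the statistical signatures the analysis
relies on, with ground-truth labels, so the classifier and kinematics can
be validated against a known answer. Each trial is planned as:

- a delay epoch with small isotropic positional tremor (SD 0.01 mm per
  sample) and two Bernoulli hazards: a false start (a reach launched
  before the go cue) and a delay drift (a slow, < 50 mm/s ramp out of the
  start target);
- a ballistic minimum-jerk submovement covering `ballistic_fraction` of
  the target distance, with isotropic endpoint noise;
- a Poisson number of corrective minimum-jerk submovements, each closing
  80% of the remaining gap after a 30 ms pause;
- a hold epoch with a Bernoulli hold-drift hazard realised as a single
  exit movement at a uniform time within the hold.

The ground-truth label follows from which termination event occurs first
under the task rules applied to the continuous plan; the sampled
trajectory is a rendering of that plan, so truth labels and rendered
trajectories agree by construction up to discretization at decision
boundaries (the classifier reproduces truth labels on ≥ 99% of
non-degenerate trials). The minimum-jerk primitive was chosen because its
symmetric velocity profile gives the ballistic-endpoint statistic an
analytic oracle; it is a standard motor-control building block, not a
claim about how any real arm moves.

Two presets ship as YAML. `paper_like` encodes reward-graded overcaution:
the ballistic fraction shortens (1.05 → 0.80 from Small to Jackpot),
corrective load and correction duration grow, and endpoint noise shrinks,
yielding success near 64/74/81/66% across Small/Medium/Large/Jackpot with
overshoot-dominated Small failures, undershoot-dominated Jackpot failures,
and median homing times rising steeply at Jackpot. `null` gives every cue
identical parameters for type-I-error checks. All generator constants are
engineering choices: the source experiments publish no generative model,
so the preset was calibrated once, by simulation, to reproduce the
qualitative profile above, and is not fitted to any dataset. Reward
magnitudes default to 0.1/0.3/0.5/3.0 mL with the largest cue on 5% of
trials — ten times the middle magnitude, matching the rare-and-large
structure that defines a Jackpot.

What the generator does *not* emulate: trial-to-trial learning or
adaptation, satiation across a session, biomechanical arm dynamics,
curved or obstacle-constrained paths, and eye-hand coordination. Passing
tests therefore demonstrate that the pipeline's statistics behave
correctly on data with the assumed two-phase structure; they cannot
certify behavior on pathologies the model excludes.

**Randomness.** A session takes one root seed; each trial derives a
private substream seed from the root and the trial counter by a fixed
arithmetic map (`derive_trial_seed()`), and all of a trial's draws occur
in a documented order before any rendering noise. Identical
`(params, seed)` give bitwise-identical sessions, single trials can be
regenerated in isolation, and label-only runs (`render = FALSE`) produce
the same labels as rendered runs.

## Data formats

The portable format is a directory of two plain CSVs — `trials.csv` (one
row per trial) and `trajectories.csv` (long-form `t`, `x`, `y` in ms and
mm, origin at the start-target center, y up) — chosen so fixtures stay
text and diffable. Deposited `.mat` kinematic files are read through a
user-supplied field map (`read_trials_mat()`), since their internal layout
varies by lab; irregular timestamps are resampled to a uniform 1 ms grid
by linear interpolation on load. Loaded trials with a `recorded_outcome`
are compared against the classifier and the recorded label takes
precedence for statistics, with disagreements surfaced in a confusion
table.

## Problem sizes and numerical choices

The shipped test suite exercises the pipeline at sizes chosen to make
Monte-Carlo conclusions stable while keeping a full run in minutes on one
CPU: 10,000-trial sweeps for the classifier-agreement and
doubling-identity properties, 200 replicates of 4,000 trials each for the
choking power and false-alarm checks, 2,000 null replicates for the
z-test's size, and 10,000 bootstrap resamples wherever SEs are reported.
Sessions render at a 2 ms sample period (500 Hz) by default; the
closed-form kinematic examples use 1 ms, where the minimum-jerk peak-speed
and homing worked examples are exact to within a sample. Degenerate
inputs are handled explicitly rather than silently: zero-trial cues,
constant samples in Welch's t, fully tied samples in the U test (p = 1),
peaks at the first sample, and trajectories ending mid-hold all either
error with a named cause or return flagged values.

## Limitations

The classifier's thresholds approximate unpublished experimental-control
rules, so on real data `recorded_outcome` should be treated as
authoritative (the package does this by default). The homing statistic is
undefined for trials that never get close to the target, so per-cue homing
medians condition on near-completion; comparisons across cues with very
different failure mixes should keep the reported exclusion tallies in
view. The generator's hazards are stationary within a session, so
time-on-task effects (fatigue, satiation) cannot be studied with it. And
the choking flag is a two-condition contrast at a fixed α — it is a
screening summary, not a substitute for inspecting the full profile.
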