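# reachpressure

Trial-level analysis of **choking under pressure** in cued-reward reaching
experiments, for motor-psychophysics and behavioral-neuroscience labs.

In these experiments a subject holds a cursor in a central start target, sees
a cue announcing the reward at stake for this trial — including a rare,
exceptionally large "Jackpot" (5% of trials, 10× the middle magnitude) — and
after a go cue must reach quickly and accurately to a peripheral target and
hold there. Performance typically follows an **inverted-U** in reward: success
rises from small to large stakes and then *falls* for the Jackpot. This
package implements the statistics that establish and dissect that effect:

- **Kinematics** — per-trial reaction time, peak speed, the *ballistic
  endpoint prediction* (mirror the vector velocity from go cue to peak speed
  about the peak time and integrate the symmetric profile:
  `x̂ = x(go) + ∫ v_mirrored dt`, which estimates where the reach would have
  landed with no visual correction), and the *homing time* (time from
  covering 2/3 of the target distance to first arriving within 1 mm of the
  target acceptance boundary).
- **Outcome classification** — exactly one label per trial from the
  exhaustive taxonomy `success`, `false_start`, `delay_drift`, `undershoot`,
  `overshoot`, `target_hold_drift`, `other`, assigned by first-violation-wins
  rules over the delay / reach / target-hold epochs.
- **Reward statistics** — per-cue success rates with 10,000-resample
  bootstrap SEs, two-proportion z-tests (pooled variance), Welch's t,
  Mann-Whitney U with medians, failure-mode decompositions that conserve the
  success-rate delta, per-session choking counts, and choice-task preference
  summaries.
- **A synthetic generator** — sessions built from minimum-jerk submovements
  with per-cue ballistic fractions, corrective-submovement loads and epoch
  hazards, carrying ground-truth labels so the whole pipeline is testable
  without experimental data. The `paper_like` preset produces the inverted-U;
  the `null` preset supports type-I-error checks.

Everything is tidyverse-shaped: trials are a tibble with a `trajectory`
list-column, every function takes a data frame first and returns a tibble,
and fitted profiles support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(reachpressure)

params  <- preset_params("paper_like")          # task + generator preset
trials  <- generate_session(params, 2000, seed = 42)
trials  <- classify_trials(trials, params$task) # adds outcome labels
profile <- choking_profile(trials, n_boot = 10000, seed = 42)
profile
#> <choking_profile>
#>      cue n_trials success_rate bootstrap_se
#>    Small      723    0.6334716   0.01792611
#>   Medium      604    0.7284768   0.01819207
#>    Large      578    0.7871972   0.01710035
#>  Jackpot       95    0.6736842   0.04823194
#> comparisons:
#>  cue_a   cue_b  delta_pp      p_value stars
#>  Small   Large -15.37256 1.718934e-09   ***
#>  Large Jackpot  11.35130 1.465415e-02     *
#> choking flag (Large > Jackpot, alpha = 0.05): TRUE
```

Success climbs from Small (63%) to Large (79%), then drops 11.4 percentage
points for the Jackpot — the choking signature, flagged because the
Large-to-Jackpot decrement is significant at α = 0.05. Which failure mode
pays for the drop?

```r
failure_mode_decomposition(profile, "Large", "Jackpot")
#>   mode              contribution_pp
#> 1 undershoot                10.7
#> 2 false_start                3.52
#> ...
```

Undershoots — reaches that stop or time out short of the target — account
for most of the decrement, the kinematic fingerprint of over-caution. The
per-trial kinematics agree:

```r
kinematic_summary(trials[1:500, ], params$task) |>
  dplyr::group_by(reward_cue) |>
  dplyr::summarise(median_homing_ms = median(homing_time, na.rm = TRUE),
                   mean_ballistic_mm = mean(ballistic_distance, na.rm = TRUE))
#>   reward_cue median_homing_ms mean_ballistic_mm
#> 1 Jackpot                 229              64.0
#> 2 Large                    62              74.4
#> 3 Medium                   42              79.4
#> 4 Small                    38              83.4
```

The ballistic component shortens and the homing phase stretches as the
stake grows: higher rewards make the launch more conservative and the final
approach longer. `autoplot(profile)`, `plot_failure_modes(profile)` and
`plot_kinematic_medians(...)` draw the corresponding figures, and
`run_analysis()` / `make_report()` execute the whole chain from a single
config, writing tidy CSV tables and a seeded run log.

Real data load through `load_trials()` — a plain-CSV directory format
(`trials.csv` + `trajectories.csv`; times ms, positions mm, origin at the
start-target center) or `.mat` kinematic files via a user-supplied field map
(`read_trials_mat()`). When trials carry a `recorded_outcome`, it takes
precedence over the classifier for statistics and disagreements are surfaced
with `confusion_table()`.

A thin command-line wrapper is included:

```sh
Rscript scripts/reachpressure-cli.R simulate --preset paper_like --n 2000 --seed 1 --out trials_dir
Rscript scripts/reachpressure-cli.R analyze  --n 2000 --seed 1 --out results_dir
Rscript scripts/reachpressure-cli.R selftest
```

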