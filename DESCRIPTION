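Package: reachpressure
Title: Reward-Graded Reach Kinematics and Choking-Under-Pressure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for cued-reward, center-out reaching experiments in
    which performance can decline when the stakes are highest ("choking under
    pressure"). Provides trial-level kinematic statistics (ballistic reach endpoint
    prediction by velocity-profile mirroring, homing time, reaction time, peak
    speed), an exhaustive trial-outcome classifier over the delay / reach /
    target-hold epochs (false start, delay drift, undershoot, overshoot, target
    hold drift), the reward-condition statistical battery (bootstrap standard
    errors, two-proportion z-tests, Welch's t, Mann-Whitney U, failure-mode
    decomposition, per-session choking counts, choice-task preference), and a
    synthetic session generator built from minimum-jerk submovements with
    ground-truth outcome labels so the whole pipeline is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
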