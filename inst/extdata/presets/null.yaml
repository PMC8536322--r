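# Null preset: every reward cue shares identical reach parameters and
# hazards, so any apparent reward effect is a false positive. Used for
# type-I-error checks of the statistical battery.
task:
  center_radius: 5.0
  target_distance: 80.0
  target_radius: 9.0
  target_angles: [0.0, 180.0]
  cue_onset_delay: 200.0
  delay_range: [300.0, 700.0]
  reach_timeout: 1000.0
  hold_duration: 400.0
globals:
  sample_period: 2.0
  rt_mean: 230.0
  rt_sd: 25.0
  rt_min: 120.0
  correction_gain: 0.8
  correction_pause: 30.0
  correction_noise_sd: 2.0
  tremor_sd: 0.01
cues:
  - cue: Small
    magnitude_ml: 0.1
    frequency: 0.35
    ballistic_fraction: 0.97
    ballistic_duration: 280.0
    n_corrections_mean: 1.0
    correction_duration: 150.0
    endpoint_noise_sd: 6.5
    false_start_hazard: 0.010
    delay_drift_hazard: 0.010
    hold_drift_hazard: 0.015
  - cue: Medium
    magnitude_ml: 0.3
    frequency: 0.30
    ballistic_fraction: 0.97
    ballistic_duration: 280.0
    n_corrections_mean: 1.0
    correction_duration: 150.0
    endpoint_noise_sd: 6.5
    false_start_hazard: 0.010
    delay_drift_hazard: 0.010
    hold_drift_hazard: 0.015
  - cue: Large
    magnitude_ml: 0.5
    frequency: 0.30
    ballistic_fraction: 0.97
    ballistic_duration: 280.0
    n_corrections_mean: 1.0
    correction_duration: 150.0
    endpoint_noise_sd: 6.5
    false_start_hazard: 0.010
    delay_drift_hazard: 0.010
    hold_drift_hazard: 0.015
  - cue: Jackpot
    magnitude_ml: 3.0
    frequency: 0.05
    ballistic_fraction: 0.97
    ballistic_duration: 280.0
    n_corrections_mean: 1.0
    correction_duration: 150.0
    endpoint_noise_sd: 6.5
    false_start_hazard: 0.010
    delay_drift_hazard: 0.010
    hold_drift_hazard: 0.015
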