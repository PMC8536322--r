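cfg90 <- task_config(target_distance = 90, target_radius = 9,
                     reach_timeout = 1200, target_angles = 0)

test_that("speed profiles recover stationary, uniform and minimum-jerk motion", {
  still <- constant_speed_trial(0, t_end = 100)
  expect_true(all(speed_profile(still$trajectory[[1]], 25)$speed == 0))

  unif <- constant_speed_trial(0.1, t_end = 500)
  sp <- speed_profile(unif$trajectory[[1]], 0)
  interior <- sp$t > 0 & sp$t < 500
  expect_equal(sp$speed[interior], rep(100, sum(interior)), tolerance = 1e-9)

  # minimum-jerk closed form: peak speed = 1.875 * amplitude / duration
  mj <- mj_trial(amp = 80, dur = 400, h = 1)
  spd <- speed_profile(mj$trajectory[[1]], 0)$speed
  expect_equal(max(spd), 1.875 * 80 / 0.4, tolerance = 0.01)

  expect_error(speed_profile(tibble::tibble(t = c(0, 1), x = c(0, 0),
                                            y = c(0, 0))), "3 samples")
})

test_that("reaction time handles ordinary, false-start and stationary trials", {
  cfg <- task_config()
  tr <- mj_trial(amp = 80, dur = 300, t_on = 550, go = 300, t_end = 1000)
  rt <- reaction_time(tr, cfg, method = "center_exit")
  # center exit happens when the 80 mm movement covers 5 mm: ~61 ms into
  # the minimum-jerk profile (s(tau) = 1/16 at tau ~ 0.205)
  expect_false(rt$rt_flagged)
  expect_gt(rt$reaction_time, 250)
  expect_lt(rt$reaction_time, 320)
  rt2 <- reaction_time(tr, cfg, method = "speed_threshold")
  expect_false(rt2$rt_flagged)
  expect_lt(abs(rt2$reaction_time - 250), 30)

  fs <- mj_trial(amp = 80, dur = 300, t_on = 100, go = 400, t_end = 800)
  rt_fs <- reaction_time(fs, cfg, method = "center_exit")
  expect_lt(rt_fs$reaction_time, 0)
  expect_true(rt_fs$rt_flagged)

  still <- constant_speed_trial(0, t_end = 400)
  rt_still <- reaction_time(still, cfg, method = "center_exit")
  expect_true(is.na(rt_still$reaction_time))
  expect_true(rt_still$rt_flagged)
})

test_that("mirrored velocity integration recovers symmetric reach endpoints", {
  # noise-free minimum-jerk: velocity is time-symmetric about the peak, so
  # the ballistic prediction must equal the actual endpoint
  tr <- mj_trial(amp = 80, dur = 400, angle = 30, go = 0, t_end = 600)
  be <- ballistic_endpoint(tr, cfg90)
  endpoint <- 80 * c(cos(pi / 6), sin(pi / 6))
  expect_false(be$ballistic_flagged)
  expect_lt(sqrt((be$ballistic_x - endpoint[1])^2 +
                   (be$ballistic_y - endpoint[2])^2), 0.1)

  # truncated at peak speed: the mirror doubles the displacement at peak
  full <- mj_trial(amp = 80, dur = 400, go = 0, t_end = 600)
  traj <- full$trajectory[[1]]
  half <- full
  keep <- traj$t <= 200 # peak of a 400 ms minimum-jerk is at midtime
  half$trajectory[[1]] <- traj[keep, ]
  be_half <- ballistic_endpoint(half, cfg90)
  expect_equal(be_half$ballistic_distance, 80, tolerance = 0.01 * 80)
})

test_that("ballistic distance matches generator ground truth at zero noise", {
  cp <- cue_params(ballistic_fraction = rep(0.7, 4),
                   n_corrections_mean = rep(0, 4),
                   endpoint_noise_sd = rep(0, 4),
                   false_start_hazard = rep(0, 4),
                   delay_drift_hazard = rep(0, 4),
                   hold_drift_hazard = rep(0, 4))
  params <- generator_params(cues = cp, tremor_sd = 0)
  tr <- generate_trial(params, "Medium", seed = 11)
  be <- ballistic_endpoint(tr, params$task)
  expect_equal(be$ballistic_distance, 0.7 * params$task$target_distance,
               tolerance = 0.01 * 0.7 * params$task$target_distance)
})

test_that("homing time matches the constant-speed worked example exactly", {
  # 90 mm at 0.1 mm/ms: homing start at 60 mm (600 ms), end within 1 mm of
  # the 9 mm acceptance boundary at 80 mm (800 ms) -> exactly 200 ms
  tr <- constant_speed_trial(0.1, t_end = 1100)
  ht <- homing_time(tr, cfg90)
  expect_true(ht$homing_defined)
  expect_identical(ht$homing_time, 200)

  short <- constant_speed_trial(0.1, t_end = 1100)
  short$trajectory[[1]]$x <- pmin(short$trajectory[[1]]$x, 45) # stops at 50%
  ht2 <- homing_time(short, cfg90)
  expect_true(is.na(ht2$homing_time))
  expect_false(ht2$homing_defined)
})

test_that("homing time shrinks with a wider proximity or a later start", {
  # both knobs tighten the measured interval: a wider acceptance region ends
  # the approach earlier, and a later start threshold begins it later
  params <- preset_params("paper_like")
  trials <- generate_session(params, 60, seed = 31)
  trials <- trials[trials$truth_label %in% c("success", "undershoot",
                                             "overshoot"), ]
  for (i in seq_len(min(nrow(trials), 30))) {
    tr <- trials[i, ]
    base <- homing_time(tr, params$task)$homing_time
    wider <- homing_time(tr, params$task, homing_proximity = 3)$homing_time
    later <- homing_time(tr, params$task,
                         homing_start_fraction = 0.75)$homing_time
    if (!is.na(base)) {
      if (!is.na(wider)) expect_lte(wider, base)
      if (!is.na(later)) expect_lte(later, base)
    }
  }
})

test_that("corrective submovements lengthen homing time in order", {
  cfg <- task_config(target_angles = 0)
  hts <- vapply(0:2, function(k) {
    homing_time(corrected_reach_trial(cfg, k), cfg)$homing_time
  }, numeric(1))
  expect_true(all(diff(hts) > 0))
})

test_that("across-cue homing ordering is robust to the start fraction", {
  params <- preset_params("paper_like")
  trials <- generate_session(params, 700, seed = 77)
  ord <- c("Small", "Medium", "Large", "Jackpot")
  med_at <- function(f) {
    ht <- vapply(seq_len(nrow(trials)), function(i) {
      homing_time(trials[i, ], params$task,
                  homing_start_fraction = f)$homing_time
    }, numeric(1))
    tapply(ht, factor(trials$reward_cue, ord), median, na.rm = TRUE)
  }
  for (f in c(1 / 2, 2 / 3, 3 / 4)) {
    m <- med_at(f)
    expect_true(all(diff(m) > 0),
                label = sprintf("medians increasing at fraction %.2f", f))
  }
})

test_that("per-trial kinematic summaries are keyed and complete", {
  params <- preset_params("paper_like")
  trials <- generate_session(params, 25, seed = 41)
  km <- kinematic_summary(trials, params$task)
  expect_equal(nrow(km), 25)
  expect_identical(km$trial_index, trials$trial_index)
  expect_true(all(km$peak_speed >= 0, na.rm = TRUE))
  expect_true(all(km$homing_time[km$homing_defined] >= 0))
})
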