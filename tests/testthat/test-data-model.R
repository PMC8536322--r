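test_that("task_config validates geometry, frequencies and delay range", {
  expect_s3_class(task_config(), "task_config")
  expect_error(task_config(target_radius = -1), "lengths")
  expect_error(task_config(homing_start_fraction = 1), "homing_start_fraction")
  expect_error(task_config(delay_range = c(500, 300)), "delay_range")
  expect_error(reward_cues(frequency = c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
  expect_silent(reward_cues(frequency = c(0.35, 0.3, 0.3, 0.05 + 1e-12)))
})

test_that("trajectory constructor rejects malformed input and resamples", {
  expect_error(trajectory(t = 1, x = 0, y = 0), "2 samples")
  expect_error(trajectory(t = c(0, 1), x = c(0, NaN), y = c(0, 0)), "finite")
  expect_error(trajectory(t = c(1, 0), x = c(0, 0), y = c(0, 0)), "increasing")
  irr <- tibble::tibble(t = c(0, 1, 3, 7, 8), x = c(0, 1, 3, 7, 8), y = 0)
  res <- resample_trajectory(irr, sample_period = 1)
  expect_equal(diff(res$t), rep(1, 8))
  expect_equal(res$x, res$t) # linear data interpolates exactly
})

test_that("write_trials / load_trials round-trips a synthetic session", {
  params <- generator_params()
  trials <- generate_session(params, 20, seed = 101)
  dir <- withr::local_tempdir()
  write_trials(trials, dir)
  back <- load_trials(dir, config = params$task)
  expect_equal(nrow(back), 20)
  for (col in c("subject_id", "reward_cue", "trial_index")) {
    expect_identical(back[[col]], trials[[col]])
  }
  for (col in c("reward_magnitude", "go_cue_time", "delay_duration",
                "trial_end_time", "truth_homing_time")) {
    expect_equal(back[[col]], trials[[col]], tolerance = 1e-12)
  }
  expect_equal(back$trajectory[[7]]$x, trials$trajectory[[7]]$x,
               tolerance = 1e-12)
  # writing the re-loaded data again is a fixed point up to float printing
  dir2 <- withr::local_tempdir()
  write_trials(back, dir2)
  back2 <- load_trials(dir2, config = params$task)
  expect_equal(back2$go_cue_time, back$go_cue_time, tolerance = 1e-12)
  expect_equal(back2$trajectory[[7]], back$trajectory[[7]], tolerance = 1e-12)
})

test_that("empty trial lists and absent recorded outcomes survive the format", {
  dir <- withr::local_tempdir()
  empty <- generate_session(generator_params(), 1, seed = 1)[0, ]
  write_trials(empty, dir)
  expect_true(file.exists(file.path(dir, "trials.csv")))
  back <- load_trials(dir)
  expect_equal(nrow(back), 0)

  trials <- generate_session(generator_params(), 3, seed = 2)
  expect_true(all(is.na(trials$recorded_outcome)))
  dir3 <- withr::local_tempdir()
  write_trials(trials, dir3)
  back3 <- load_trials(dir3)
  expect_true(all(is.na(back3$recorded_outcome)))
})

test_that("validation errors name the offending field or trial", {
  trials <- generate_session(generator_params(), 3, seed = 3)
  dir <- withr::local_tempdir()
  write_trials(trials, dir)
  meta <- readr::read_csv(file.path(dir, "trials.csv"), show_col_types = FALSE)
  readr::write_csv(meta[, setdiff(names(meta), "go_cue_time")],
                   file.path(dir, "trials.csv"))
  expect_error(load_trials(dir), "go_cue_time")

  dir2 <- withr::local_tempdir()
  bad <- trials
  bad$trajectory[[2]]$x[5] <- NaN
  write_trials(bad, dir2)
  expect_error(load_trials(dir2), "trial_index 2")

  expect_error(load_trials(withr::local_tempdir()), "trials.csv")
  cfg <- task_config(reward_cues = reward_cues(cue = c("A", "B", "C", "D")))
  dir3 <- withr::local_tempdir()
  write_trials(trials, dir3)
  expect_error(load_trials(dir3, config = cfg), "not in task config")
})

test_that("mat reader maps fields through a user dictionary", {
  mat <- tempfile(fileext = ".mat")
  py <- paste(
    "import numpy as np, sys",
    "from scipy.io import savemat",
    "n = 2",
    "tr = np.empty(n, object); xs = np.empty(n, object); ys = np.empty(n, object)",
    "for i in range(n):",
    "    t = np.arange(0, 50.0, 1.0)",
    "    tr[i] = t; xs[i] = 0.1 * t + i; ys[i] = 0.0 * t",
    "savemat(sys.argv[1], {'idx': np.array([1, 2]),",
    "                      'cue': np.array(['Small', 'Jackpot'], dtype=object),",
    "                      'go': np.array([10.0, 12.0]),",
    "                      'tvec': tr, 'xvec': xs, 'yvec': ys})",
    sep = "\n")
  status <- system2("python", c("-c", shQuote(py), shQuote(mat)))
  expect_equal(status, 0)
  fmap <- c(trial_index = "idx", reward_cue = "cue", go_cue_time = "go",
            t = "tvec", x = "xvec", y = "yvec")
  trials <- load_trials(mat, format = "mat", field_map = fmap)
  expect_equal(nrow(trials), 2)
  expect_identical(trials$reward_cue, c("Small", "Jackpot"))
  expect_equal(trials$go_cue_time, c(10, 12))
  expect_equal(trials$trajectory[[2]]$x[1], 1)
  expect_error(read_trials_mat(mat, fmap[-3]), "go_cue_time")
})

test_that("outcome labels map onto task epochs", {
  m <- epoch_of_failure(c("false_start", "delay_drift", "undershoot",
                          "overshoot", "target_hold_drift", "success",
                          "other"))
  expect_identical(m$epoch, c("delay", "delay", "reach", "reach",
                              "target_hold", "none", "none"))
  expect_identical(m$flagged, c(rep(FALSE, 6), TRUE))
  expect_error(epoch_of_failure("banana"), "unknown outcome")
})
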