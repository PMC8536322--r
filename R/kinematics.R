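#' Smoothed speed profile of a trajectory
#'
#' Central-difference velocity (one-sided at the edges), moving-average
#' smoothed over `smoothing_window`, returned as the Euclidean speed in
#' mm/s. The output has one row per input sample.
#'
#' @param traj Trajectory tibble (`t` ms, `x`/`y` mm; uniform sampling).
#' @param smoothing_window Moving-average window (ms); 0 disables smoothing.
#' @return A tibble with columns `t` (ms), `vx`, `vy`, `speed` (mm/s).
#' @export
speed_profile <- function(traj, smoothing_window = 25) {
  n <- nrow(traj)
  if (is.null(traj) || n < 3) abort("speed_profile needs at least 3 samples")
  h <- trajectory_period(traj)
  vx <- central_diff(traj$x, h)
  vy <- central_diff(traj$y, h)
  if (smoothing_window > 0) {
    w <- max(1L, round(smoothing_window / h))
    if (w %% 2 == 0) w <- w + 1L
    if (w > 1) {
      vx <- moving_average(vx, w)
      vy <- moving_average(vy, w)
    }
  }
  spd <- sqrt(vx^2 + vy^2) * 1000
  tibble(t = traj$t, vx = vx * 1000, vy = vy * 1000, speed = spd)
}

central_diff <- function(x, h) {
  n <- length(x)
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) / h
  v[n] <- (x[n] - x[n - 1]) / h
  if (n > 2) v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * h)
  v
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, w) {
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Raw (unsmoothed) central-difference vector velocity in mm/ms.
raw_velocity <- function(traj) {
  h <- trajectory_period(traj)
  cbind(central_diff(traj$x, h), central_diff(traj$y, h))
}

reach_window_idx <- function(traj, go, deadline) {
  which(traj$t >= go & traj$t <= deadline)
}

#' Reaction time of a single trial
#'
#' Time from the go cue to movement initiation. `center_exit` takes the
#' first time the cursor leaves the start target; `speed_threshold` takes
#' the first time speed exceeds a fraction of that trial's peak speed. Both
#' searches run over the whole trial so that movements initiated before the
#' go cue (false starts) yield negative, flagged values.
#'
#' @param trial One row of a trials tibble (or a list with `trajectory` and
#'   `go_cue_time`).
#' @param config A [task_config()].
#' @param method `"center_exit"` or `"speed_threshold"`.
#' @param speed_fraction Fraction of trial peak speed for the threshold
#'   method.
#' @param smoothing_window Passed to [speed_profile()].
#' @return A one-row tibble: `reaction_time` (ms, `NA` if undefined),
#'   `rt_flagged` (`TRUE` when undefined or pre-go).
#' @export
reaction_time <- function(trial, config, method = c("center_exit",
                                                    "speed_threshold"),
                          speed_fraction = 0.1, smoothing_window = 25) {
  method <- match.arg(method)
  traj <- trial$trajectory[[1]]
  if (is.null(traj)) abort("trial has no trajectory")
  go <- trial$go_cue_time
  if (method == "center_exit") {
    r <- sqrt(traj$x^2 + traj$y^2)
    t_hit <- first_or_na(traj$t[r > config$center_radius])
  } else {
    sp <- speed_profile(traj, smoothing_window)
    peak <- max(sp$speed)
    if (peak <= 0) {
      t_hit <- NA_real_
    } else {
      t_hit <- first_or_na(sp$t[sp$speed > speed_fraction * peak])
    }
  }
  rt <- t_hit - go
  tibble(reaction_time = rt, rt_flagged = is.na(rt) | rt < 0)
}

#' Ballistic reach endpoint prediction
#'
#' Estimates where a reach would have landed without visual-feedback
#' correction. The vector velocity from the go cue to the time of peak speed
#' is reflected about the peak time (the peak sample used once); the
#' resulting time-symmetric profile is integrated trapezoidally, and the
#' prediction is the position at the go cue plus that displacement. For a
#' reach whose velocity profile really is symmetric (e.g. an uncorrected
#' minimum-jerk movement) the prediction equals the true endpoint.
#'
#' @inheritParams reaction_time
#' @param smoothing_window Smoothing used only to locate the peak (ms); the
#'   integrated velocities are unsmoothed central differences.
#' @return A one-row tibble: `ballistic_x`, `ballistic_y` (mm),
#'   `ballistic_distance` (mm from the start-target center), `peak_speed`
#'   (mm/s), `time_of_peak` (ms), `ballistic_flagged` (`TRUE` when the peak
#'   is at the first post-go sample, a degenerate mirror).
#' @export
ballistic_endpoint <- function(trial, config, smoothing_window = 25) {
  traj <- trial$trajectory[[1]]
  if (is.null(traj)) abort("trial has no trajectory")
  go <- trial$go_cue_time
  deadline <- go + config$reach_timeout
  idx <- reach_window_idx(traj, go, deadline)
  if (length(idx) < 3) {
    return(tibble(ballistic_x = NA_real_, ballistic_y = NA_real_,
                  ballistic_distance = NA_real_, peak_speed = NA_real_,
                  time_of_peak = NA_real_, ballistic_flagged = TRUE))
  }
  sp <- speed_profile(traj, smoothing_window)
  k_rel <- which.max(sp$speed[idx]) # earliest maximum by which.max
  k <- idx[k_rel]
  p_go <- c(traj$x[idx[1]], traj$y[idx[1]])
  peak_speed <- sp$speed[k]
  if (k_rel == 1) {
    return(tibble(ballistic_x = p_go[1], ballistic_y = p_go[2],
                  ballistic_distance = sqrt(sum(p_go^2)),
                  peak_speed = peak_speed, time_of_peak = traj$t[k],
                  ballistic_flagged = TRUE))
  }
  h <- trajectory_period(traj)
  v <- raw_velocity(traj)[idx[1]:k, , drop = FALSE] # mm/ms, go..peak
  disp <- mirrored_integral(v, h)
  pt <- p_go + disp
  tibble(ballistic_x = pt[1], ballistic_y = pt[2],
         ballistic_distance = sqrt(sum(pt^2)),
         peak_speed = peak_speed, time_of_peak = traj$t[k],
         ballistic_flagged = FALSE)
}

# Trapezoidal integral of [v_0..v_k, v_{k-1}..v_0] (peak sample used once).
# Algebraically equal to 2 * trapezoid(v_0..v_k); kept in mirrored form to
# match the definition, with the doubling identity asserted in tests.
mirrored_integral <- function(v, h) {
  k <- nrow(v)
  vm <- rbind(v, v[seq(k - 1, 1), , drop = FALSE])
  n <- nrow(vm)
  colSums((vm[-1, , drop = FALSE] + vm[-n, , drop = FALSE]) / 2) * h
}

#' Homing time of a single trial
#'
#' Time spent in the final approach: from the first moment the cursor has
#' covered `homing_start_fraction` of the distance to the target (radial
#' projection by default) to the first subsequent moment it comes within
#' `homing_proximity` of the target (acceptance boundary by default). The
#' search is truncated at the reach timeout plus `homing_buffer`, which lets
#' near-miss undershoot failures contribute a homing time. Either event
#' failing to occur yields an undefined, flagged result.
#'
#' @inheritParams reaction_time
#' @param homing_start_fraction,homing_proximity,homing_reference,
#'   progress_measure Optional overrides of the corresponding
#'   [task_config()] fields.
#' @return A one-row tibble: `homing_time` (ms or `NA`), `homing_defined`.
#' @export
homing_time <- function(trial, config,
                        homing_start_fraction = NULL,
                        homing_proximity = NULL,
                        homing_reference = NULL,
                        progress_measure = NULL) {
  f <- homing_start_fraction %||% config$homing_start_fraction
  prox <- homing_proximity %||% config$homing_proximity
  ref <- homing_reference %||% config$homing_reference
  meas <- progress_measure %||% config$progress_measure
  traj <- trial$trajectory[[1]]
  if (is.null(traj)) abort("trial has no trajectory")
  go <- trial$go_cue_time
  t_max <- go + config$reach_timeout + config$homing_buffer
  idx <- which(traj$t >= go & traj$t <= t_max)
  if (length(idx) < 2) {
    return(tibble(homing_time = NA_real_, homing_defined = FALSE))
  }
  tc <- target_center(config, trial$target_angle)
  x <- traj$x[idx]
  y <- traj$y[idx]
  tt <- traj$t[idx]
  p0 <- c(x[1], y[1])
  if (meas == "projection") {
    u <- tc - p0
    u <- u / sqrt(sum(u^2))
    progress <- ((x - p0[1]) * u[1] + (y - p0[2]) * u[2]) / config$target_distance
  } else {
    step <- sqrt(diff(x)^2 + diff(y)^2)
    progress <- c(0, cumsum(step)) / config$target_distance
    progress <- cummax(progress)
  }
  i_start <- first_or_na(which(progress >= f))
  if (is.na(i_start)) {
    return(tibble(homing_time = NA_real_, homing_defined = FALSE))
  }
  R_acc <- if (ref == "boundary") config$target_radius + prox else prox
  dtc <- sqrt((x - tc[1])^2 + (y - tc[2])^2)
  i_end <- first_or_na(which(dtc <= R_acc & seq_along(dtc) >= i_start))
  if (is.na(i_end)) {
    return(tibble(homing_time = NA_real_, homing_defined = FALSE))
  }
  tibble(homing_time = tt[i_end] - tt[i_start], homing_defined = TRUE)
}

#' Per-trial kinematic summary table
#'
#' Applies [reaction_time()], [ballistic_endpoint()] and [homing_time()] to
#' every trial and returns one flat row per trial, keyed by subject, session
#' and trial index — ready to join back onto the trials tibble or write as
#' CSV.
#'
#' @param trials A trials tibble (e.g. from [generate_session()] or
#'   [load_trials()]).
#' @param config A [task_config()].
#' @param rt_method Reaction-time method, see [reaction_time()].
#' @param smoothing_window Speed-profile smoothing window (ms).
#' @return A tibble with one row per trial: keys, `reaction_time`,
#'   `rt_flagged`, `peak_speed`, `time_of_peak`, `ballistic_x/y`,
#'   `ballistic_distance`, `ballistic_flagged`, `homing_time`,
#'   `homing_defined`.
#' @export
kinematic_summary <- function(trials, config, rt_method = "center_exit",
                              smoothing_window = 25) {
  out <- purrr::map(seq_len(nrow(trials)), function(i) {
    trial <- trials[i, ]
    dplyr::bind_cols(
      tibble(subject_id = trial$subject_id, session_id = trial$session_id,
             trial_index = trial$trial_index, reward_cue = trial$reward_cue),
      reaction_time(trial, config, method = rt_method,
                    smoothing_window = smoothing_window),
      ballistic_endpoint(trial, config, smoothing_window = smoothing_window),
      homing_time(trial, config)
    )
  })
  dplyr::bind_rows(out)
}
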