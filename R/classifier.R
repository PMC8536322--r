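#' Classify a single trial's outcome
#'
#' Assigns exactly one label from the exhaustive taxonomy by evaluating the
#' task rules in temporal order (first violation wins):
#'
#' 1. `false_start` — speed exceeds `init_speed_threshold` before the go cue
#'    (a reach launched early);
#' 2. `delay_drift` — the cursor leaves the start target before the go cue
#'    without reach-speed movement;
#' 3. `success` — the cursor stops inside the reach target before the reach
#'    timeout and remains there through the full hold;
#' 4. `overshoot` — the cursor passes through or beyond the target without a
#'    qualifying stop;
#' 5. `undershoot` — the reach times out short of the target or mid-flight;
#' 6. `target_hold_drift` — the cursor stops in the target but exits before
#'    the hold completes;
#' 7. `other` — anything else (e.g. a trajectory ending before the go cue),
#'    flagged.
#'
#' A qualifying stop is a sample inside the target with speed below
#' `stop_speed_fraction` of the trial's peak speed that stays inside for
#' `stop_dwell` ms, which separates a genuine stop from a slow transit
#' through the target.
#'
#' @param trial One row of a trials tibble.
#' @param config A [task_config()].
#' @param init_speed_threshold Pre-go speed (mm/s) that counts as a launched
#'   reach.
#' @param stop_speed_fraction Fraction of trial peak speed below which the
#'   cursor counts as stopped.
#' @param stop_dwell Minimum time (ms) a stop must stay inside the target to
#'   qualify.
#' @param smoothing_window Speed-profile smoothing window (ms).
#' @return A one-row tibble: `outcome`, `outcome_flagged`.
#' @export
classify_trial <- function(trial, config, init_speed_threshold = 50,
                           stop_speed_fraction = 0.1, stop_dwell = 50,
                           smoothing_window = 25) {
  traj <- trial$trajectory[[1]]
  if (is.null(traj)) abort("trial has no trajectory")
  go <- trial$go_cue_time
  sp <- speed_profile(traj, smoothing_window)
  r_center <- sqrt(traj$x^2 + traj$y^2)
  pre <- traj$t < go

  # (1)/(2) delay-epoch violations, earlier event wins
  t_fs <- first_or_na(traj$t[pre & sp$speed > init_speed_threshold])
  t_dd <- first_or_na(traj$t[pre & r_center > config$center_radius])
  if (!is.na(t_fs) || !is.na(t_dd)) {
    lab <- if (is.na(t_dd) || (!is.na(t_fs) && t_fs <= t_dd)) {
      "false_start"
    } else {
      "delay_drift"
    }
    return(tibble(outcome = lab, outcome_flagged = FALSE))
  }
  deadline <- go + config$reach_timeout
  win <- reach_window_idx(traj, go, deadline)
  if (length(win) < 2) {
    return(tibble(outcome = "other", outcome_flagged = TRUE))
  }
  tc <- target_center(config, trial$target_angle)
  dtc <- sqrt((traj$x - tc[1])^2 + (traj$y - tc[2])^2)
  inside <- dtc <= config$target_radius
  peak <- max(sp$speed[win])
  stop_thr <- stop_speed_fraction * peak
  h <- trajectory_period(traj)
  dwell_n <- max(1L, ceiling(stop_dwell / h))

  # (3)/(6) qualifying stop inside the target before the deadline
  cand <- win[inside[win] & sp$speed[win] <= stop_thr]
  t_stop <- NA_real_
  for (j in cand) {
    span <- j:min(length(inside), j + dwell_n)
    if (all(inside[span])) { t_stop <- traj$t[j]; break }
  }
  if (!is.na(t_stop)) {
    hold_idx <- which(traj$t > t_stop & traj$t <= t_stop + config$hold_duration)
    if (!length(hold_idx) ||
        max(traj$t) < t_stop + config$hold_duration - h / 2) {
      return(tibble(outcome = "other", outcome_flagged = TRUE))
    }
    if (any(!inside[hold_idx])) {
      return(tibble(outcome = "target_hold_drift", outcome_flagged = FALSE))
    }
    return(tibble(outcome = "success", outcome_flagged = FALSE))
  }

  # (4)/(5) reach-epoch failures
  entered <- which(inside[win])
  if (length(entered)) {
    first_in <- entered[1]
    exited_after <- any(!inside[win[first_in:length(win)]])
    lab <- if (exited_after) "overshoot" else "undershoot"
    return(tibble(outcome = lab, outcome_flagged = FALSE))
  }
  p0 <- c(traj$x[win[1]], traj$y[win[1]])
  u <- tc - p0
  u <- u / sqrt(sum(u^2))
  progress <- ((traj$x[win] - p0[1]) * u[1] + (traj$y[win] - p0[2]) * u[2]) /
    config$target_distance
  lab <- if (max(progress) >= 1) "overshoot" else "undershoot"
  tibble(outcome = lab, outcome_flagged = FALSE)
}

#' Classify every trial of a trials tibble
#'
#' Adds `outcome` and `outcome_flagged` columns. When a `recorded_outcome`
#' column is present (real data), an `outcome_agrees` column compares the
#' classifier's label against the recording, and `outcome_final` takes the
#' recorded label where available (recorded outcomes are authoritative for
#' statistics); otherwise `outcome_final` equals `outcome`.
#'
#' @inheritParams classify_trial
#' @param trials A trials tibble.
#' @return `trials` with classification columns appended.
#' @export
classify_trials <- function(trials, config, init_speed_threshold = 50,
                            stop_speed_fraction = 0.1, stop_dwell = 50,
                            smoothing_window = 25) {
  res <- dplyr::bind_rows(purrr::map(seq_len(nrow(trials)), function(i) {
    classify_trial(trials[i, ], config,
                   init_speed_threshold = init_speed_threshold,
                   stop_speed_fraction = stop_speed_fraction,
                   stop_dwell = stop_dwell,
                   smoothing_window = smoothing_window)
  }))
  out <- dplyr::bind_cols(trials, res)
  if ("recorded_outcome" %in% names(out)) {
    out <- out |>
      mutate(
        outcome_agrees = ifelse(is.na(.data$recorded_outcome), NA,
                                .data$recorded_outcome == .data$outcome),
        outcome_final = dplyr::coalesce(.data$recorded_outcome, .data$outcome)
      )
  } else {
    out$outcome_final <- out$outcome
  }
  out
}

#' Confusion table between classifier and recorded/truth labels
#'
#' Cross-tabulates the classifier's labels against a reference column
#' (recorded outcomes for real data, `truth_label` for synthetic data).
#'
#' @param trials A classified trials tibble (see [classify_trials()]).
#' @param reference Name of the reference label column.
#' @return A tibble with `reference`, `classified`, `n`, sorted by count.
#' @export
confusion_table <- function(trials, reference = "truth_label") {
  if (!reference %in% names(trials)) {
    abort(sprintf("no column '%s' in trials", reference))
  }
  trials |>
    dplyr::count(reference = .data[[reference]],
                 classified = .data$outcome, name = "n") |>
    arrange(dplyr::desc(.data$n))
}
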