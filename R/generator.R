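#' Per-cue generator parameters
#'
#' One row per reward cue. The generative model is a two-phase reach: a
#' ballistic minimum-jerk submovement covering `ballistic_fraction` of the
#' target distance (plus isotropic endpoint noise), followed by a Poisson
#' number of corrective minimum-jerk submovements that each close a fixed
#' fraction of the remaining gap. Reward-graded behavior is expressed by
#' varying these fields across cues: shorter ballistic fractions and more
#' corrections emulate increasingly cautious reaches.
#'
#' @param cue Cue labels (must match the task's reward cues).
#' @param ballistic_fraction Fraction of the target distance covered by the
#'   ballistic submovement, in (0, 1.5].
#' @param ballistic_duration Ballistic submovement duration (ms).
#' @param n_corrections_mean Poisson mean of the corrective submovement count.
#' @param correction_duration Duration of each corrective submovement (ms).
#' @param endpoint_noise_sd Isotropic SD of the ballistic endpoint (mm).
#' @param false_start_hazard,delay_drift_hazard,hold_drift_hazard Per-trial
#'   probabilities of the corresponding failure event, each in `[0, 1]`.
#' @return A tibble with one row per cue.
#' @export
cue_params <- function(cue = c("Small", "Medium", "Large", "Jackpot"),
                       ballistic_fraction = c(1.05, 1.00, 0.93, 0.80),
                       ballistic_duration = c(260, 280, 300, 320),
                       n_corrections_mean = c(0.55, 0.7, 1.1, 1.2),
                       correction_duration = c(140, 150, 160, 230),
                       endpoint_noise_sd = c(8.2, 7.5, 6.2, 5),
                       false_start_hazard = c(0.010, 0.010, 0.010, 0.030),
                       delay_drift_hazard = c(0.010, 0.010, 0.010, 0.020),
                       hold_drift_hazard = c(0.010, 0.010, 0.015, 0.030)) {
  out <- tibble(cue = as.character(cue),
                ballistic_fraction = ballistic_fraction,
                ballistic_duration = ballistic_duration,
                n_corrections_mean = n_corrections_mean,
                correction_duration = correction_duration,
                endpoint_noise_sd = endpoint_noise_sd,
                false_start_hazard = false_start_hazard,
                delay_drift_hazard = delay_drift_hazard,
                hold_drift_hazard = hold_drift_hazard)
  validate_cue_params(out)
  out
}

validate_cue_params <- function(cp) {
  hz <- c(cp$false_start_hazard, cp$delay_drift_hazard, cp$hold_drift_hazard)
  if (any(hz < 0 | hz > 1)) abort("hazards must be probabilities in [0, 1]")
  if (any(cp$ballistic_fraction <= 0 | cp$ballistic_fraction > 1.5)) {
    abort("ballistic_fraction must be in (0, 1.5]")
  }
  if (any(cp$ballistic_duration <= 0) || any(cp$correction_duration <= 0)) {
    abort("durations must be > 0")
  }
  if (any(cp$n_corrections_mean < 0) || any(cp$endpoint_noise_sd < 0)) {
    abort("n_corrections_mean and endpoint_noise_sd must be >= 0")
  }
  invisible(cp)
}

#' Generator parameters for synthetic sessions
#'
#' Bundles the task configuration, the per-cue reach model ([cue_params()])
#' and the global motor constants of the generator.
#'
#' @param task A [task_config()].
#' @param cues Per-cue parameters, see [cue_params()]. Cue labels must match
#'   `task$reward_cues$cue`.
#' @param sample_period Trajectory sample period (ms).
#' @param rt_mean,rt_sd,rt_min Reaction time distribution: normal with mean
#'   `rt_mean`, SD `rt_sd`, truncated below at `rt_min` (ms).
#' @param correction_gain Fraction of the remaining gap closed per corrective
#'   submovement.
#' @param correction_pause Pause between successive submovements (ms).
#' @param correction_noise_sd Isotropic endpoint SD of corrections (mm).
#' @param tremor_sd Per-sample isotropic positional tremor SD (mm).
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(task = task_config(),
                             cues = cue_params(),
                             sample_period = 2,
                             rt_mean = 230, rt_sd = 25, rt_min = 120,
                             correction_gain = 0.8,
                             correction_pause = 30,
                             correction_noise_sd = 2,
                             tremor_sd = 0.01) {
  if (!inherits(task, "task_config")) abort("task must be a task_config")
  validate_cue_params(cues)
  missing_cues <- setdiff(task$reward_cues$cue, cues$cue)
  if (length(missing_cues)) {
    abort(sprintf("cues missing generator parameters: %s",
                  paste(missing_cues, collapse = ", ")))
  }
  stopifnot(sample_period > 0, rt_sd >= 0, rt_min > 0,
            correction_gain > 0, correction_gain <= 1,
            correction_pause >= 0, correction_noise_sd >= 0, tremor_sd >= 0)
  structure(list(task = task, cues = cues, sample_period = sample_period,
                 rt_mean = rt_mean, rt_sd = rt_sd, rt_min = rt_min,
                 correction_gain = correction_gain,
                 correction_pause = correction_pause,
                 correction_noise_sd = correction_noise_sd,
                 tremor_sd = tremor_sd),
            class = "generator_params")
}

#' Load a named generator preset
#'
#' Presets ship as plain YAML under `extdata/presets`. `"paper_like"` encodes
#' reward-graded overcaution (ballistic shortening, homing lengthening, an
#' undershoot-prone Jackpot) that produces an inverted-U success profile with
#' its maximum at Large; `"null"` gives every cue identical parameters and is
#' used for type-I-error checks.
#'
#' @param name Preset name, or a path to a preset YAML file.
#' @param task Optional [task_config()] override; defaults to the preset's.
#' @return A `generator_params` object.
#' @export
preset_params <- function(name = c("paper_like", "null"), task = NULL) {
  path <- if (file.exists(name[1])) {
    name[1]
  } else {
    name <- match.arg(name)
    system.file("extdata", "presets", paste0(name, ".yaml"),
                package = "reachpressure", mustWork = TRUE)
  }
  spec <- yaml::read_yaml(path)
  cue_tbl <- dplyr::bind_rows(lapply(spec$cues, as_tibble))
  if (is.null(task)) {
    tk <- spec$task
    task <- task_config(
      center_radius = tk$center_radius, target_distance = tk$target_distance,
      target_radius = tk$target_radius, target_angles = unlist(tk$target_angles),
      cue_onset_delay = tk$cue_onset_delay, delay_range = unlist(tk$delay_range),
      reach_timeout = tk$reach_timeout, hold_duration = tk$hold_duration,
      reward_cues = reward_cues(cue = cue_tbl$cue,
                                magnitude_ml = cue_tbl$magnitude_ml,
                                frequency = cue_tbl$frequency)
    )
  }
  g <- spec$globals
  generator_params(
    task = task,
    cues = cue_params(
      cue = cue_tbl$cue,
      ballistic_fraction = cue_tbl$ballistic_fraction,
      ballistic_duration = cue_tbl$ballistic_duration,
      n_corrections_mean = cue_tbl$n_corrections_mean,
      correction_duration = cue_tbl$correction_duration,
      endpoint_noise_sd = cue_tbl$endpoint_noise_sd,
      false_start_hazard = cue_tbl$false_start_hazard,
      delay_drift_hazard = cue_tbl$delay_drift_hazard,
      hold_drift_hazard = cue_tbl$hold_drift_hazard
    ),
    sample_period = g$sample_period, rt_mean = g$rt_mean, rt_sd = g$rt_sd,
    rt_min = g$rt_min, correction_gain = g$correction_gain,
    correction_pause = g$correction_pause,
    correction_noise_sd = g$correction_noise_sd, tremor_sd = g$tremor_sd
  )
}

#' Draw a reproducible reward-cue sequence
#'
#' i.i.d. draws from the configured cue frequencies (a rare Jackpot appears
#' on about 5% of trials under the default schedule).
#'
#' @param params A `generator_params` object.
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @return Character vector of cue labels of length `n_trials`.
#' @export
draw_reward_sequence <- function(params, n_trials, seed) {
  stopifnot(n_trials >= 1)
  cues <- params$task$reward_cues
  if (abs(sum(cues$frequency) - 1) > 1e-9) {
    abort("reward cue frequencies must sum to 1")
  }
  with_seed(seed, sample(cues$cue, n_trials, replace = TRUE,
                         prob = cues$frequency))
}

# ---- internal plan machinery -------------------------------------------------

seg_min_dist <- function(p0, p1, q) {
  d <- p1 - p0
  L2 <- sum(d^2)
  s <- if (L2 == 0) 0 else max(0, min(1, sum((q - p0) * d) / L2))
  sqrt(sum((p0 + s * d - q)^2))
}

# Smallest s in (0, 1] where |p0 + s*(p1-p0) - q| = R, or NA.
seg_circle_entry <- function(p0, p1, q, R) {
  d <- p1 - p0
  f <- p0 - q
  a <- sum(d^2)
  if (a == 0) return(NA_real_)
  b <- 2 * sum(f * d)
  cc <- sum(f^2) - R^2
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(NA_real_)
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  roots <- roots[roots > 0 & roots <= 1]
  if (length(roots)) min(roots) else NA_real_
}

# Plan a single trial: all stochastic draws happen here, in a fixed order,
# so a rendered and a label-only run of the same substream agree.
plan_trial <- function(params, cue_row, seed) {
  cfg <- params$task
  set.seed(seed)
  delay <- runif(1, cfg$delay_range[1], cfg$delay_range[2])
  angle <- cfg$target_angles[sample.int(length(cfg$target_angles), 1)]
  u <- runif(3) # false start, delay drift, hold drift
  rt <- max(params$rt_min, rnorm(1, params$rt_mean, params$rt_sd))
  eps_ball <- rnorm(2) * cue_row$endpoint_noise_sd
  n_corr <- rpois(1, cue_row$n_corrections_mean)
  eps_corr <- if (n_corr > 0) {
    matrix(rnorm(2 * n_corr) * params$correction_noise_sd, ncol = 2)
  } else {
    matrix(numeric(0), ncol = 2)
  }
  extra <- runif(2)

  go <- cfg$cue_onset_delay + delay
  dirv <- c(cos(angle * pi / 180), sin(angle * pi / 180))
  tc <- dirv * cfg$target_distance
  deadline <- go + cfg$reach_timeout
  inside <- function(p) sqrt(sum((p - tc)^2)) <= cfg$target_radius

  plan <- list(delay = delay, angle = angle, go = go, tc = tc, dirv = dirv,
               seed = seed, segs = list(), stop_time = NA_real_,
               drift_at = NA_real_, drift_dir = NA_real_,
               truth_ballistic = c(NA_real_, NA_real_))

  if (u[1] < cue_row$false_start_hazard) {
    # reach launched before the go cue
    lead <- 60 + extra[1] * (max(0, min(300, 0.8 * delay) - 60))
    onset <- go - lead
    e1 <- dirv * (cue_row$ballistic_fraction * cfg$target_distance) + eps_ball
    plan$segs <- list(list(type = "mj", p0 = c(0, 0), p1 = e1,
                           t_on = onset, dur = cue_row$ballistic_duration))
    plan$label <- "false_start"
    plan$truth_ballistic <- e1
    plan$trial_end <- onset + cue_row$ballistic_duration
    plan$render_end <- plan$trial_end + 100
    return(plan)
  }
  if (u[2] < cue_row$delay_drift_hazard) {
    # slow drift out of the start target before the go cue
    exit_time <- go - (50 + extra[1] * max(0, 0.8 * delay - 50))
    drift_start <- max(20, exit_time - 400)
    v <- cfg$center_radius / (exit_time - drift_start) # mm/ms, slow
    ddir <- c(cos(extra[2] * 2 * pi), sin(extra[2] * 2 * pi))
    travel_end <- exit_time + 150
    p1 <- ddir * v * (travel_end - drift_start)
    plan$segs <- list(list(type = "lin", p0 = c(0, 0), p1 = p1,
                           t_on = drift_start, dur = travel_end - drift_start))
    plan$label <- "delay_drift"
    plan$trial_end <- exit_time
    plan$render_end <- travel_end + 50
    return(plan)
  }

  # ordinary reach epoch
  onset <- go + rt
  e1 <- dirv * (cue_row$ballistic_fraction * cfg$target_distance) + eps_ball
  segs <- list(list(type = "mj", p0 = c(0, 0), p1 = e1,
                    t_on = onset, dur = cue_row$ballistic_duration))
  plan$truth_ballistic <- e1
  cur <- e1
  t_cur <- onset + cue_row$ballistic_duration
  transit <- FALSE
  note_transit <- function(p0, p1) {
    (seg_min_dist(p0, p1, tc) <= cfg$target_radius && !inside(p1)) ||
      (sum(p1 * dirv) >= cfg$target_distance && !inside(p1))
  }
  stop_time <- NA_real_
  if (inside(e1)) {
    if (t_cur <= deadline) stop_time <- t_cur
  } else {
    transit <- transit || note_transit(c(0, 0), e1)
    if (n_corr > 0) {
      for (j in seq_len(n_corr)) {
        t_on <- t_cur + params$correction_pause
        p1 <- cur + params$correction_gain * (tc - cur) + eps_corr[j, ]
        segs[[length(segs) + 1]] <- list(type = "mj", p0 = cur, p1 = p1,
                                         t_on = t_on,
                                         dur = cue_row$correction_duration)
        t_end <- t_on + cue_row$correction_duration
        if (inside(p1)) {
          if (t_end <= deadline) stop_time <- t_end
          t_cur <- t_end
          break
        }
        transit <- transit || note_transit(cur, p1)
        cur <- p1
        t_cur <- t_end
      }
    }
  }
  plan$segs <- segs
  plan$stop_time <- stop_time

  if (!is.na(stop_time)) {
    if (u[3] < cue_row$hold_drift_hazard) {
      plan$label <- "target_hold_drift"
      # drift must leave the target well before the hold elapses; the exit
      # movement itself takes ~170 ms, hence the 330 ms head margin
      plan$drift_at <- stop_time + 80 +
        extra[1] * max(0, cfg$hold_duration - 330)
      plan$drift_dir <- extra[2] * 2 * pi
      ddir <- c(cos(plan$drift_dir), sin(plan$drift_dir))
      p_stop <- segs[[length(segs)]]$p1
      plan$segs[[length(segs) + 1]] <- list(
        type = "mj", p0 = p_stop, p1 = p_stop + ddir * 2.5 * cfg$target_radius,
        t_on = plan$drift_at, dur = 250)
      plan$trial_end <- plan$drift_at + 250
      plan$render_end <- plan$trial_end + 50
    } else {
      plan$label <- "success"
      plan$trial_end <- stop_time + cfg$hold_duration
      plan$render_end <- plan$trial_end + 2 * params$sample_period
    }
  } else {
    plan$label <- if (transit) "overshoot" else "undershoot"
    plan$trial_end <- deadline
    plan$render_end <- max(t_cur, deadline) + cfg$homing_buffer
  }
  plan
}

# Render a plan into a sampled trajectory. Tremor draws happen after all
# plan draws, so labels are unaffected by whether a trial is rendered.
render_plan <- function(params, plan) {
  sp <- params$sample_period
  tt <- seq(0, plan$render_end, by = sp)
  n <- length(tt)
  px <- numeric(n)
  py <- numeric(n)
  for (seg in plan$segs) {
    idx <- which(tt >= seg$t_on)
    if (!length(idx)) next
    frac <- (tt[idx] - seg$t_on) / seg$dur
    s <- if (seg$type == "mj") mj_s(frac) else pmin(pmax(frac, 0), 1)
    px[idx] <- seg$p0[1] + (seg$p1[1] - seg$p0[1]) * s
    py[idx] <- seg$p0[2] + (seg$p1[2] - seg$p0[2]) * s
  }
  if (params$tremor_sd > 0) {
    px <- px + rnorm(n) * params$tremor_sd
    py <- py + rnorm(n) * params$tremor_sd
  }
  trajectory(tt, px, py)
}

# Ground-truth homing time from the continuous plan (reach trials only):
# first crossing of the progress threshold to first entry into the homing
# proximity region, truncated at timeout + buffer. Mirrors homing_time()
# but uses the noise-free piecewise minimum-jerk plan analytically.
plan_homing_time <- function(params, plan) {
  cfg <- params$task
  if (!plan$label %in% c("success", "undershoot", "overshoot",
                         "target_hold_drift")) {
    return(NA_real_)
  }
  dirv <- plan$dirv
  tc <- plan$tc
  f_target <- cfg$homing_start_fraction * cfg$target_distance
  R_acc <- if (cfg$homing_reference == "boundary") {
    cfg$target_radius + cfg$homing_proximity
  } else {
    cfg$homing_proximity
  }
  t_max <- plan$go + cfg$reach_timeout + cfg$homing_buffer
  seg_time <- function(seg, s) seg$t_on + mj_s_inv(s) * seg$dur
  start_t <- NA_real_
  for (seg in plan$segs) {
    if (seg$type != "mj") next
    a0 <- sum(seg$p0 * dirv)
    a1 <- sum(seg$p1 * dirv)
    if (a0 >= f_target) { start_t <- seg$t_on; break }
    if (a1 >= f_target && a1 > a0) {
      start_t <- seg_time(seg, (f_target - a0) / (a1 - a0))
      break
    }
  }
  if (is.na(start_t) || start_t > t_max) return(NA_real_)
  end_t <- NA_real_
  for (seg in plan$segs) {
    seg_end <- seg$t_on + seg$dur
    if (seg_end < start_t) next
    if (sqrt(sum((seg$p0 - tc)^2)) <= R_acc && seg$t_on >= start_t) {
      end_t <- seg$t_on
      break
    }
    s_in <- seg_circle_entry(seg$p0, seg$p1, tc, R_acc)
    if (!is.na(s_in)) {
      cand <- seg_time(seg, s_in)
      if (cand >= start_t) { end_t <- cand; break }
      # already inside before start: still counts at the start time
      end_t <- start_t
      break
    }
  }
  if (is.na(end_t) || end_t > t_max) return(NA_real_)
  max(0, end_t - start_t)
}


#' Generate one synthetic trial
#'
#' Draws a full trial plan (delay, hazards, reaction time, ballistic
#' endpoint, corrective submovements) from a per-trial random substream and
#' optionally renders the sampled trajectory. The returned row carries the
#' ground-truth outcome label and ground-truth kinematics implied by the
#' plan, for use as a test oracle.
#'
#' @param params A [generator_params()] object.
#' @param cue Reward cue label.
#' @param seed Integer seed for this trial's substream.
#' @param render If `FALSE`, skip trajectory rendering (the `trajectory`
#'   column holds `NULL`); labels and truth kinematics are unchanged.
#' @param subject_id,session_id,trial_index Identifiers for the output row.
#' @return A one-row trials tibble (see [generate_session()] for columns).
#' @export
generate_trial <- function(params, cue, seed, render = TRUE,
                           subject_id = "synthetic", session_id = "s1",
                           trial_index = 1L) {
  out <- generate_trials_for_cues(params, cue, function(i) seed,
                                  render = render, truth_homing = TRUE,
                                  subject_id = subject_id,
                                  session_id = session_id)
  out$trial_index <- as.integer(trial_index)
  out
}

# Shared trial loop: cue labels + a seed function -> trials tibble.
generate_trials_for_cues <- function(params, cues, seed_for, render,
                                     truth_homing, subject_id, session_id) {
  n <- length(cues)
  bad <- setdiff(unique(cues), params$cues$cue)
  if (length(bad)) abort(sprintf("unknown cue '%s'", bad[1]))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  cue_rows <- split(params$cues, params$cues$cue)
  mag <- params$task$reward_cues$magnitude_ml[
    match(cues, params$task$reward_cues$cue)]
  angle <- delay <- go <- tend <- bx <- by <- homing <- numeric(n)
  label <- character(n)
  trajs <- vector("list", n)
  for (i in seq_len(n)) {
    plan <- plan_trial(params, cue_rows[[cues[i]]], seed_for(i))
    angle[i] <- plan$angle
    delay[i] <- plan$delay
    go[i] <- plan$go
    tend[i] <- plan$trial_end
    label[i] <- plan$label
    bx[i] <- plan$truth_ballistic[1]
    by[i] <- plan$truth_ballistic[2]
    homing[i] <- if (truth_homing) plan_homing_time(params, plan) else NA_real_
    if (render) trajs[[i]] <- render_plan(params, plan)
  }
  tibble(
    subject_id = subject_id, session_id = session_id,
    trial_index = seq_len(n), reward_cue = cues, reward_magnitude = mag,
    target_angle = angle, delay_duration = delay, go_cue_time = go,
    trial_end_time = tend, recorded_outcome = NA_character_,
    truth_label = label, truth_ballistic_x = bx, truth_ballistic_y = by,
    truth_homing_time = homing, trajectory = trajs
  )
}

#' Generate a synthetic session
#'
#' Draws the reward sequence from the configured cue frequencies, then
#' generates independent trials, each from a substream derived from the root
#' seed and the trial counter: the whole session is reproducible from
#' `(params, seed)`, and trial `i` alone is reproducible via
#' `generate_trial(params, cue, derive_trial_seed(seed, i))`.
#'
#' @inheritParams generate_trial
#' @param n_trials Number of trials (>= 1).
#' @param seed Root integer seed.
#' @param truth_homing Compute the ground-truth homing time from the
#'   continuous plan (a root-finding step per trial; defaults to `render` so
#'   large label-only simulations stay fast).
#' @return A trials tibble with one row per trial: identifiers, cue and
#'   magnitude, target angle, event times (ms), `recorded_outcome` (`NA` for
#'   synthetic data), ground-truth columns (`truth_label`,
#'   `truth_ballistic_x/y`, `truth_homing_time`) and the `trajectory`
#'   list-column.
#' @export
generate_session <- function(params, n_trials, seed, render = TRUE,
                             truth_homing = render,
                             subject_id = "synthetic", session_id = "s1") {
  stopifnot(n_trials >= 1)
  cues <- draw_reward_sequence(params, n_trials, seed)
  generate_trials_for_cues(params, cues,
                           function(i) derive_trial_seed(seed, i),
                           render = render, truth_homing = truth_homing,
                           subject_id = subject_id, session_id = session_id)
}

#' Per-trial substream seed
#'
#' The arithmetic map from a session's root seed and a trial counter to that
#' trial's private seed. Exposed so single trials of a session can be
#' regenerated in isolation.
#'
#' @param seed Root seed.
#' @param i Trial counter (1-based).
#' @return An integer seed below 2^31.
#' @export
derive_trial_seed <- function(seed, i) derive_seed(seed, i)
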