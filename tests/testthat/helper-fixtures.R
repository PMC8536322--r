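# Shared fixtures: hand-built trajectories and an independent rule-by-rule
# outcome oracle, all constructed in code at test time.

mj_position <- function(amp_vec, dur, t, t_on = 0) {
  tau <- pmin(pmax((t - t_on) / dur, 0), 1)
  s <- tau^3 * (10 - 15 * tau + 6 * tau^2)
  cbind(amp_vec[1] * s, amp_vec[2] * s)
}

# A pure minimum-jerk reach of amplitude `amp` (mm) at `angle` deg,
# movement onset at `t_on`, rest tail afterwards; go cue at `go`.
mj_trial <- function(amp, dur, angle = 0, t_on = 0, go = 0, h = 1,
                     t_end = t_on + dur + 100, target_angle = angle) {
  tt <- seq(0, t_end, by = h)
  dirv <- c(cos(angle * pi / 180), sin(angle * pi / 180))
  pos <- mj_position(dirv * amp, dur, tt, t_on)
  tibble::tibble(
    subject_id = "fix", session_id = "s1", trial_index = 1L,
    reward_cue = "Large", reward_magnitude = 0.5, target_angle = target_angle,
    delay_duration = max(go - 200, 0), go_cue_time = go,
    trial_end_time = t_end, recorded_outcome = NA_character_,
    trajectory = list(trajectory(tt, pos[, 1], pos[, 2]))
  )
}

# Constant-velocity trial along +x starting at the go cue.
constant_speed_trial <- function(speed_mm_per_ms, t_end, go = 0, h = 1) {
  tt <- seq(0, t_end, by = h)
  x <- pmax(tt - go, 0) * speed_mm_per_ms
  tibble::tibble(
    subject_id = "fix", session_id = "s1", trial_index = 1L,
    reward_cue = "Large", reward_magnitude = 0.5, target_angle = 0,
    delay_duration = 0, go_cue_time = go, trial_end_time = t_end,
    recorded_outcome = NA_character_,
    trajectory = list(trajectory(tt, x, numeric(length(tt))))
  )
}

# A reach built from a ballistic submovement plus k corrective submovements
# that split the remaining distance evenly (the reach only attains the
# target on the last correction), noise-free. Each extra correction delays
# the final approach, so homing time must grow with k.
corrected_reach_trial <- function(config, k, go = 300,
                                  bd = 300, cd = 150, pause = 30, h = 1) {
  D <- config$target_distance
  bf <- if (k == 0) 1.0 else 0.8
  t_end <- go + 200 + bd + k * (pause + cd) + 300
  tt <- seq(0, t_end, by = h)
  x <- numeric(length(tt))
  onset <- go + 200
  p1 <- bf * D
  segs <- list(list(p0 = 0, p1 = p1, t_on = onset, dur = bd))
  cur <- p1
  t_cur <- onset + bd
  for (j in seq_len(k)) {
    t_on <- t_cur + pause
    nxt <- bf * D + (D - bf * D) * j / k
    segs[[length(segs) + 1]] <- list(p0 = cur, p1 = nxt, t_on = t_on, dur = cd)
    cur <- nxt
    t_cur <- t_on + cd
  }
  for (seg in segs) {
    idx <- tt >= seg$t_on
    tau <- pmin((tt[idx] - seg$t_on) / seg$dur, 1)
    s <- tau^3 * (10 - 15 * tau + 6 * tau^2)
    x[idx] <- seg$p0 + (seg$p1 - seg$p0) * s
  }
  tibble::tibble(
    subject_id = "fix", session_id = "s1", trial_index = 1L,
    reward_cue = "Large", reward_magnitude = 0.5, target_angle = 0,
    delay_duration = go - 200, go_cue_time = go, trial_end_time = t_end,
    recorded_outcome = NA_character_,
    trajectory = list(trajectory(tt, x, numeric(length(tt))))
  )
}

# Independent rule-by-rule outcome oracle: plain loops over samples, written
# without reusing any classifier internals. Used to cross-check
# classify_trial on constructed and generated trajectories.
oracle_classify <- function(trial, config, init_thr = 50, stop_frac = 0.1,
                            dwell = 50) {
  traj <- trial$trajectory[[1]]
  go <- trial$go_cue_time
  h <- median(diff(traj$t))
  n <- nrow(traj)
  vx <- c(diff(traj$x)[1], (traj$x[min(3, n):n] - traj$x[1:(n - 2)]) / 2,
          diff(traj$x)[n - 1]) / h
  vy <- c(diff(traj$y)[1], (traj$y[min(3, n):n] - traj$y[1:(n - 2)]) / 2,
          diff(traj$y)[n - 1]) / h
  w <- round(25 / h)
  if (w %% 2 == 0) w <- w + 1
  sm <- function(v) stats::filter(v, rep(1 / w, w), sides = 2)
  vxs <- sm(vx); vys <- sm(vy)
  vxs[is.na(vxs)] <- vx[is.na(vxs)]
  vys[is.na(vys)] <- vy[is.na(vys)]
  speed <- sqrt(vxs^2 + vys^2) * 1000
  tc <- c(cos(trial$target_angle * pi / 180),
          sin(trial$target_angle * pi / 180)) * config$target_distance
  d_center <- sqrt(traj$x^2 + traj$y^2)
  d_target <- sqrt((traj$x - tc[1])^2 + (traj$y - tc[2])^2)
  for (i in seq_len(n)) {
    if (traj$t[i] >= go) break
    if (speed[i] > init_thr) return("false_start")
    if (d_center[i] > config$center_radius) return("delay_drift")
  }
  deadline <- go + config$reach_timeout
  win <- which(traj$t >= go & traj$t <= deadline)
  if (length(win) < 2) return("other")
  peak <- max(speed[win])
  dwell_n <- ceiling(dwell / h)
  t_stop <- NA
  for (i in win) {
    if (d_target[i] <= config$target_radius && speed[i] <= stop_frac * peak) {
      ok <- TRUE
      for (j in i:min(n, i + dwell_n)) {
        if (d_target[j] > config$target_radius) { ok <- FALSE; break }
      }
      if (ok) { t_stop <- traj$t[i]; break }
    }
  }
  if (!is.na(t_stop)) {
    if (traj$t[n] < t_stop + config$hold_duration - h / 2) return("other")
    for (j in which(traj$t > t_stop & traj$t <= t_stop + config$hold_duration)) {
      if (d_target[j] > config$target_radius) return("target_hold_drift")
    }
    return("success")
  }
  inside_win <- d_target[win] <= config$target_radius
  if (any(inside_win)) {
    first_in <- which(inside_win)[1]
    if (any(!inside_win[first_in:length(win)])) return("overshoot")
    return("undershoot")
  }
  p0 <- c(traj$x[win[1]], traj$y[win[1]])
  u <- (tc - p0) / sqrt(sum((tc - p0)^2))
  prog <- ((traj$x[win] - p0[1]) * u[1] + (traj$y[win] - p0[2]) * u[2]) /
    config$target_distance
  if (max(prog) >= 1) "overshoot" else "undershoot"
}

# Brute-force Mann-Whitney U: pairwise count with half credit for ties.
brute_force_u <- function(a, b) {
  u <- 0
  for (ai in a) for (bi in b) {
    u <- u + (ai > bi) + 0.5 * (ai == bi)
  }
  u
}

# Exact two-sided permutation p-value for a 2x2 table by |p1 - p2|
# (hypergeometric enumeration of k1 given fixed margins).
exact_permutation_p <- function(k1, n1, k2, n2) {
  k <- k1 + k2
  obs <- abs(k1 / n1 - k2 / n2)
  ks <- max(0, k - n2):min(k, n1)
  probs <- stats::dhyper(ks, n1, n2, k)
  sum(probs[abs(ks / n1 - (k - ks) / n2) >= obs - 1e-12])
}

# Peak speed of a minimum-jerk movement, mm/ms.
mj_peak_speed_mm_ms <- function(amp, dur) 1.875 * amp / dur
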