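#' Reward cue table
#'
#' One row per reward cue: label, water volume (mL) and presentation
#' frequency. The default four-cue schedule makes the Jackpot rare (5% of
#' trials) and 10 times the Medium magnitude, with the remaining probability
#' split over the ordinary cues.
#'
#' @param cue Character vector of cue labels.
#' @param magnitude_ml Reward volume per cue (mL).
#' @param frequency Presentation probability per cue; must sum to 1.
#' @return A tibble with columns `cue`, `magnitude_ml`, `frequency`.
#' @export
reward_cues <- function(cue = c("Small", "Medium", "Large", "Jackpot"),
                        magnitude_ml = c(0.1, 0.3, 0.5, 3.0),
                        frequency = c(0.35, 0.30, 0.30, 0.05)) {
  if (length(cue) != length(magnitude_ml) || length(cue) != length(frequency)) {
    abort("cue, magnitude_ml and frequency must have equal length")
  }
  if (anyDuplicated(cue)) abort("reward cue labels must be unique")
  if (abs(sum(frequency) - 1) > 1e-9) {
    abort(sprintf("reward cue frequencies must sum to 1 (got %.12f)",
                  sum(frequency)))
  }
  if (any(frequency < 0)) abort("reward cue frequencies must be non-negative")
  tibble(cue = as.character(cue),
         magnitude_ml = as.double(magnitude_ml),
         frequency = as.double(frequency))
}

#' Task geometry and timing configuration
#'
#' Describes one speed + accuracy session layout: a central start target, a
#' peripheral reach target at one of several angles, a variable delay, a
#' timed reach and a 400 ms target hold. All lengths are mm, all times ms.
#'
#' @param center_radius Radius of the central start target (mm).
#' @param target_distance Distance from center to the reach-target center (mm).
#' @param target_radius Radius of the reach target (mm).
#' @param target_angles Possible target directions (degrees).
#' @param cue_onset_delay Time from trial start to reach-target onset (ms).
#' @param delay_range `c(min, max)` of the variable delay between cue onset
#'   and the go cue (ms).
#' @param reach_timeout Time allowed after the go cue to stop in the target (ms).
#' @param hold_duration Required hold inside the reach target (ms).
#' @param homing_start_fraction Fraction of the target distance at which the
#'   homing phase starts (default 2/3).
#' @param homing_proximity Proximity (mm) that ends the homing phase.
#' @param homing_buffer Extra search time past the reach timeout (ms) so that
#'   undershoot failures that nearly reach the target still get a homing time.
#' @param homing_reference `"boundary"` measures `homing_proximity` to the
#'   target acceptance boundary (distance to target center <= target_radius +
#'   proximity, the default); `"center"` measures it to the target center.
#' @param progress_measure `"projection"` (default) measures reach progress as
#'   the projection onto the start-to-target axis; `"path"` uses cumulative
#'   path length.
#' @param reward_cues Cue schedule, see [reward_cues()].
#' @return An object of class `task_config`.
#' @export
task_config <- function(center_radius = 5,
                        target_distance = 80,
                        target_radius = 9,
                        target_angles = c(0, 180),
                        cue_onset_delay = 200,
                        delay_range = c(300, 700),
                        reach_timeout = 1000,
                        hold_duration = 400,
                        homing_start_fraction = 2 / 3,
                        homing_proximity = 1,
                        homing_buffer = 150,
                        homing_reference = c("boundary", "center"),
                        progress_measure = c("projection", "path"),
                        reward_cues = reachpressure::reward_cues()) {
  homing_reference <- match.arg(homing_reference)
  progress_measure <- match.arg(progress_measure)
  lengths <- c(center_radius = center_radius, target_distance = target_distance,
               target_radius = target_radius, homing_proximity = homing_proximity)
  if (any(lengths <= 0)) {
    abort(sprintf("all lengths must be > 0 (offending: %s)",
                  paste(names(lengths)[lengths <= 0], collapse = ", ")))
  }
  if (homing_start_fraction <= 0 || homing_start_fraction >= 1) {
    abort("homing_start_fraction must be in (0, 1)")
  }
  if (length(delay_range) != 2 || delay_range[1] > delay_range[2]) {
    abort("delay_range must be c(min, max) with min <= max")
  }
  stopifnot(cue_onset_delay >= 0, reach_timeout > 0, hold_duration > 0,
            homing_buffer >= 0, length(target_angles) >= 1)
  cues <- reward_cues
  if (!all(c("cue", "magnitude_ml", "frequency") %in% names(cues))) {
    abort("reward_cues must have columns cue, magnitude_ml, frequency")
  }
  if (abs(sum(cues$frequency) - 1) > 1e-9) {
    abort("reward cue frequencies must sum to 1")
  }
  structure(list(
    center_radius = center_radius,
    target_distance = target_distance,
    target_radius = target_radius,
    target_angles = as.double(target_angles),
    cue_onset_delay = cue_onset_delay,
    delay_range = as.double(delay_range),
    reach_timeout = reach_timeout,
    hold_duration = hold_duration,
    homing_start_fraction = homing_start_fraction,
    homing_proximity = homing_proximity,
    homing_buffer = homing_buffer,
    homing_reference = homing_reference,
    progress_measure = progress_measure,
    reward_cues = cues
  ), class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  start target: radius %.1f mm; reach target: radius %.1f mm at %.1f mm\n",
              x$center_radius, x$target_radius, x$target_distance))
  cat(sprintf("  angles: %s deg\n", paste(x$target_angles, collapse = ", ")))
  cat(sprintf("  delay %g-%g ms after %g ms cue onset; reach timeout %g ms; hold %g ms\n",
              x$delay_range[1], x$delay_range[2], x$cue_onset_delay,
              x$reach_timeout, x$hold_duration))
  cat(sprintf("  homing: start at %.3f of distance, within %g mm of target %s (+%g ms buffer)\n",
              x$homing_start_fraction, x$homing_proximity, x$homing_reference,
              x$homing_buffer))
  cat("  reward cues:\n")
  print(as.data.frame(x$reward_cues), row.names = FALSE)
  invisible(x)
}

# Target-center coordinates for an angle in degrees.
target_center <- function(config, angle_deg) {
  a <- angle_deg * pi / 180
  c(cos(a), sin(a)) * config$target_distance
}

#' Outcome labels and failure epochs
#'
#' The exhaustive trial-outcome taxonomy: `success` plus the five failure
#' modes (`false_start`, `delay_drift`, `undershoot`, `overshoot`,
#' `target_hold_drift`) and a catch-all `other`.
#'
#' @return Character vector of the seven labels.
#' @export
outcome_labels <- function() {
  c("success", "false_start", "delay_drift", "undershoot", "overshoot",
    "target_hold_drift", "other")
}

#' Map an outcome label to its task epoch
#'
#' Delay-epoch failures are false starts and delay drifts; reach-epoch
#' failures are undershoots and overshoots; target-hold drifts belong to the
#' target-hold epoch. Successes map to `none`; `other` maps to `none` with a
#' flag.
#'
#' @param label Character vector of outcome labels.
#' @return A tibble with columns `label`, `epoch`, `flagged`.
#' @export
epoch_of_failure <- function(label) {
  if (!all(label %in% outcome_labels())) {
    bad <- setdiff(unique(label), outcome_labels())
    abort(sprintf("unknown outcome label(s): %s", paste(bad, collapse = ", ")))
  }
  epoch <- dplyr::case_when(
    label %in% c("false_start", "delay_drift") ~ "delay",
    label %in% c("undershoot", "overshoot") ~ "reach",
    label == "target_hold_drift" ~ "target_hold",
    TRUE ~ "none"
  )
  tibble(label = label, epoch = epoch, flagged = label == "other")
}
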