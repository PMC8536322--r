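#' Run the full analysis pipeline
#'
#' One call from raw trials to result bundle: load (or generate) trials,
#' classify outcomes, compute per-trial kinematics, then the reward
#' statistics. Writes tidy CSV tables plus a run log into `out_dir` and
#' returns the bundle invisibly. Given the same configuration and seed the
#' bundle is bit-for-bit reproducible; input data files are never modified.
#'
#' @param config A run configuration: a named list (or path to a YAML file)
#'   with elements
#'   \describe{
#'     \item{source}{either `list(type = "synthetic", preset = "paper_like",
#'       n_trials = 2000)` or `list(type = "trials", path = <dir>)`}
#'     \item{task}{optional; arguments for [task_config()] (ignored for
#'       synthetic presets, which carry their own task)}
#'     \item{analysis}{optional; `n_boot` (default 10000), `alpha` (0.05),
#'       `ordering`, `rt_method`}
#'   }
#' @param seed Integer seed for generation and bootstrapping.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return Invisibly, a list of class `reach_bundle`: `trials` (classified),
#'   `metrics`, `profile`, `sessions`, `config`, `seed`.
#' @export
run_analysis <- function(config, seed = 1, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("no such config file: '%s'", config))
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$source$type)) {
    abort("config$source$type must be 'synthetic' or 'trials'")
  }
  analysis <- config$analysis %||% list()
  n_boot <- analysis$n_boot %||% 10000
  alpha <- analysis$alpha %||% 0.05
  rt_method <- analysis$rt_method %||% "center_exit"

  if (config$source$type == "synthetic") {
    preset <- config$source$preset %||% "paper_like"
    params <- preset_params(preset)
    n_trials <- config$source$n_trials %||% 2000
    task <- params$task
    trials <- generate_session(params, n_trials, seed,
                               subject_id = config$source$subject_id %||%
                                 "synthetic")
  } else if (config$source$type == "trials") {
    task <- do.call(task_config, config$task %||% list())
    trials <- load_trials(config$source$path,
                          format = config$source$format %||% "csv",
                          config = task)
  } else {
    abort(sprintf("unknown source type '%s'", config$source$type))
  }
  ordering <- analysis$ordering %||%
    intersect(c("Small", "Medium", "Large", "Jackpot"),
              unique(trials$reward_cue))

  trials <- classify_trials(trials, task)
  metrics <- kinematic_summary(trials, task, rt_method = rt_method)
  profile <- choking_profile(trials, ordering = ordering, n_boot = n_boot,
                             seed = seed, alpha = alpha)
  sessions <- session_choking_counts(trials, alpha = alpha)

  bundle <- structure(list(trials = trials, metrics = metrics,
                           profile = profile, sessions = sessions,
                           task = task, config = config, seed = seed),
                      class = "reach_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$metrics, file.path(out_dir, "trial_metrics.csv"))
  readr::write_csv(bundle$profile$stats,
                   file.path(out_dir, "condition_stats.csv"))
  readr::write_csv(bundle$profile$comparisons,
                   file.path(out_dir, "comparisons.csv"))
  readr::write_csv(bundle$sessions$sessions,
                   file.path(out_dir, "session_choking.csv"))
  log_lines <- c(
    sprintf("reachpressure %s", as.character(utils::packageVersion("reachpressure"))),
    sprintf("R %s", as.character(getRversion())),
    sprintf("seed: %d", bundle$seed),
    sprintf("config_hash: %s", rlang::hash(bundle$config)),
    sprintf("n_trials: %d", nrow(bundle$trials)),
    sprintf("choking: %s", bundle$profile$choking)
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Human-readable report from a result bundle
#'
#' Deterministic summary of a [run_analysis()] bundle: the per-cue success
#' curve, stacked failure-mode proportions and kinematic medians as ggplot
#' objects, plus a text summary.
#'
#' @param bundle A `reach_bundle` from [run_analysis()].
#' @return A list with `text` (character vector) and `plots` (named list of
#'   ggplot objects: `success_curve`, `failure_modes`, `homing_medians`).
#' @export
make_report <- function(bundle) {
  needed <- c("trials", "metrics", "profile", "sessions")
  missing_parts <- needed[!vapply(needed, function(nm) {
    !is.null(bundle[[nm]])
  }, logical(1))]
  if (length(missing_parts)) {
    abort(sprintf("bundle is incomplete; missing: %s",
                  paste(missing_parts, collapse = ", ")))
  }
  st <- bundle$profile$stats
  cmp <- bundle$profile$comparisons
  text <- c(
    sprintf("Trials analysed: %d", nrow(bundle$trials)),
    sprintf("Success rates: %s",
            paste(sprintf("%s %.1f%% (n=%d)", st$cue, 100 * st$success_rate,
                          st$n_trials), collapse = ", ")),
    sprintf("Comparisons: %s",
            paste(sprintf("%s-%s %+.1f pp (p=%.3g%s)", cmp$cue_a, cmp$cue_b,
                          cmp$delta_pp, cmp$p_value,
                          ifelse(cmp$stars == "ns", "", paste0(", ", cmp$stars))),
                  collapse = "; ")),
    sprintf("Choking flag: %s", bundle$profile$choking)
  )
  list(text = text,
       plots = list(success_curve = ggplot2::autoplot(bundle$profile),
                    failure_modes = plot_failure_modes(bundle$profile),
                    homing_medians = plot_kinematic_medians(
                      bundle$metrics, "homing_time",
                      ordering = bundle$profile$ordering)))
}

#' @export
print.reach_bundle <- function(x, ...) {
  cat("<reach_bundle>\n")
  cat(sprintf("  %d trials, seed %d\n", nrow(x$trials), x$seed))
  print(x$profile)
  invisible(x)
}
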