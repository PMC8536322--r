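TRIAL_FIELDS <- c("subject_id", "session_id", "trial_index", "reward_cue",
                  "reward_magnitude", "target_angle", "delay_duration",
                  "go_cue_time", "trial_end_time", "recorded_outcome")

#' Write trials to the portable on-disk format
#'
#' The portable format is a directory holding two plain CSVs:
#' `trials.csv` (one row per trial: the metadata fields, `NA` for an absent
#' recorded outcome) and `trajectories.csv` (long form: `subject_id`,
#' `session_id`, `trial_index`, `t`, `x`, `y`; times ms, positions mm).
#' `load_trials()` on the written directory reproduces the input.
#'
#' @param trials A trials tibble (ground-truth columns, if present, are
#'   written too and restored on load).
#' @param path Directory to write into (created if needed).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(sprintf("cannot create directory '%s'", path))
  keep <- intersect(c(TRIAL_FIELDS, "truth_label", "truth_ballistic_x",
                      "truth_ballistic_y", "truth_homing_time"),
                    names(trials))
  readr::write_csv(trials[, keep], file.path(path, "trials.csv"), na = "")
  traj_long <- if (nrow(trials)) {
    trials |>
      select("subject_id", "session_id", "trial_index", "trajectory") |>
      filter(!purrr::map_lgl(.data$trajectory, is.null)) |>
      tidyr::unnest("trajectory")
  } else {
    tibble(subject_id = character(), session_id = character(),
           trial_index = integer(), t = double(), x = double(), y = double())
  }
  readr::write_csv(traj_long, file.path(path, "trajectories.csv"), na = "")
  invisible(path)
}

#' Load trials from disk
#'
#' Reads the portable CSV directory format written by [write_trials()]
#' (`format = "csv"`), or a MATLAB `.mat` file through a user-supplied field
#' map (`format = "mat"`, see [read_trials_mat()]). Trajectories with
#' irregular timestamps are resampled to a uniform period by linear
#' interpolation; loaded trials are validated (mandatory fields present,
#' finite coordinates, cues drawn from the active task configuration).
#'
#' @param path Directory (csv) or file (mat) to read.
#' @param format `"csv"` or `"mat"`.
#' @param config Optional [task_config()]; when given, reward cues are
#'   checked against its cue table.
#' @param sample_period Uniform resampling period for irregular trajectories
#'   (ms).
#' @param ... Passed to [read_trials_mat()] for `format = "mat"`.
#' @return A validated trials tibble.
#' @export
load_trials <- function(path, format = c("csv", "mat"), config = NULL,
                        sample_period = 1, ...) {
  format <- match.arg(format)
  trials <- if (format == "csv") {
    load_trials_csv(path)
  } else {
    read_trials_mat(path, ...)
  }
  validate_trials(trials, config = config, sample_period = sample_period)
}

load_trials_csv <- function(path) {
  meta_path <- file.path(path, "trials.csv")
  traj_path <- file.path(path, "trajectories.csv")
  if (!file.exists(meta_path) || !file.exists(traj_path)) {
    abort(sprintf("'%s' does not contain trials.csv and trajectories.csv",
                  path))
  }
  meta <- readr::read_csv(meta_path, show_col_types = FALSE,
                          col_types = readr::cols(
                            subject_id = "c", session_id = "c",
                            reward_cue = "c", recorded_outcome = "c",
                            truth_label = "c", trial_index = "i",
                            .default = "d"))
  missing_fields <- setdiff(TRIAL_FIELDS, names(meta))
  if (length(missing_fields)) {
    abort(sprintf("trials.csv is missing mandatory field(s): %s",
                  paste(missing_fields, collapse = ", ")))
  }
  traj <- readr::read_csv(traj_path, show_col_types = FALSE,
                          col_types = readr::cols(subject_id = "c",
                                                  session_id = "c",
                                                  trial_index = "i",
                                                  .default = "d"))
  nested <- traj |>
    tidyr::nest(trajectory = c("t", "x", "y"))
  out <- meta |>
    left_join(nested, by = c("subject_id", "session_id", "trial_index"))
  if (!"trajectory" %in% names(out)) out$trajectory <- list(NULL)
  out
}

validate_trials <- function(trials, config = NULL, sample_period = 1) {
  missing_fields <- setdiff(TRIAL_FIELDS, names(trials))
  if (length(missing_fields)) {
    abort(sprintf("trials are missing mandatory field(s): %s",
                  paste(missing_fields, collapse = ", ")))
  }
  if (!is.null(config)) {
    bad <- setdiff(unique(trials$reward_cue), config$reward_cues$cue)
    if (length(bad)) {
      abort(sprintf("reward cue(s) not in task config: %s",
                    paste(bad, collapse = ", ")))
    }
  }
  if (nrow(trials) && "trajectory" %in% names(trials)) {
    trials$trajectory <- purrr::map2(
      trials$trajectory, trials$trial_index,
      function(tr, idx) {
        if (is.null(tr) || !nrow(tr)) return(NULL)
        if (any(!is.finite(tr$x)) || any(!is.finite(tr$y)) ||
            any(!is.finite(tr$t))) {
          abort(sprintf(
            "non-finite trajectory coordinates in trial_index %d", idx))
        }
        if (nrow(tr) < 2) {
          abort(sprintf("trial_index %d: trajectory has < 2 samples", idx))
        }
        if (is.unsorted(tr$t, strictly = TRUE)) {
          abort(sprintf("trial_index %d: timestamps not increasing", idx))
        }
        if (!is_uniform(tr$t)) {
          resample_trajectory(trajectory(tr$t, tr$x, tr$y), sample_period)
        } else {
          trajectory(tr$t, tr$x, tr$y)
        }
      })
  }
  as_tibble(trials)
}

#' Read trials from a MATLAB .mat file
#'
#' Deposited kinematic data typically arrives as `.mat` files whose internal
#' layout varies by lab, so the reader is driven by a field map from the
#' package's trial fields to the variable names inside the file. The file is
#' converted through the system's Python (`scipy.io.loadmat`); per-trial
#' trajectory arrays are matched by the mapped `t`/`x`/`y` fields (cell
#' arrays or ragged object arrays, one entry per trial).
#'
#' @param path Path to the `.mat` file.
#' @param field_map Named character vector mapping package fields
#'   (`subject_id`, `session_id`, `trial_index`, `reward_cue`,
#'   `reward_magnitude`, `target_angle`, `delay_duration`, `go_cue_time`,
#'   `trial_end_time`, `recorded_outcome`, `t`, `x`, `y`) to MAT variable
#'   names. Unmapped optional fields are filled with `NA`.
#' @param python Python executable used for the conversion.
#' @return A trials tibble (unvalidated; [load_trials()] validates).
#' @export
read_trials_mat <- function(path, field_map, python = "python") {
  if (!file.exists(path)) abort(sprintf("no such file: '%s'", path))
  needed <- c("trial_index", "reward_cue", "go_cue_time", "t", "x", "y")
  missing_fields <- setdiff(needed, names(field_map))
  if (length(missing_fields)) {
    abort(sprintf("field_map is missing mandatory field(s): %s",
                  paste(missing_fields, collapse = ", ")))
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  script <- paste(
    "import sys, json",
    "import numpy as np",
    "from scipy.io import loadmat",
    "path, out = sys.argv[1], sys.argv[2]",
    "fmap = json.loads(sys.argv[3])",
    "mat = loadmat(path, squeeze_me=True)",
    "def col(name):",
    "    v = mat[name]",
    "    if isinstance(v, np.ndarray) and v.dtype == object:",
    "        return [np.asarray(e).ravel().tolist() for e in v]",
    "    return np.asarray(v).ravel().tolist()",
    "res = {k: col(v) for k, v in fmap.items() if v in mat}",
    "json.dump(res, open(out, 'w'))",
    sep = "\n")
  status <- system2(python, c("-c", shQuote(script), shQuote(path),
                              shQuote(tmp),
                              shQuote(jsonlite::toJSON(as.list(field_map),
                                                       auto_unbox = TRUE))))
  if (status != 0 || !file.exists(tmp)) {
    abort("python/scipy conversion of the .mat file failed")
  }
  raw <- jsonlite::read_json(tmp, simplifyVector = TRUE, simplifyMatrix = FALSE)
  got <- names(raw)
  missing_fields <- setdiff(needed, got)
  if (length(missing_fields)) {
    abort(sprintf(".mat file lacks mapped variable(s) for: %s",
                  paste(missing_fields, collapse = ", ")))
  }
  n <- length(raw$trial_index)
  grab <- function(field, default) {
    if (field %in% got) raw[[field]] else rep(default, n)
  }
  tibble(
    subject_id = as.character(grab("subject_id", "unknown")),
    session_id = as.character(grab("session_id", "s1")),
    trial_index = as.integer(raw$trial_index),
    reward_cue = as.character(raw$reward_cue),
    reward_magnitude = as.double(grab("reward_magnitude", NA_real_)),
    target_angle = as.double(grab("target_angle", NA_real_)),
    delay_duration = as.double(grab("delay_duration", NA_real_)),
    go_cue_time = as.double(raw$go_cue_time),
    trial_end_time = as.double(grab("trial_end_time", NA_real_)),
    recorded_outcome = as.character(grab("recorded_outcome", NA_character_)),
    trajectory = purrr::pmap(list(raw$t, raw$x, raw$y), function(t, x, y) {
      tibble(t = as.double(unlist(t)), x = as.double(unlist(x)),
             y = as.double(unlist(y)))
    })
  )
}
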