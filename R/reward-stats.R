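#' Per-condition success statistics with bootstrap SE
#'
#' Success rate for one reward cue with a resampling standard error: trials
#' are resampled with replacement (same n) `n_boot` times, the rate is
#' recomputed for each resample, and the SE is the SD of those bootstrap
#' rates. Failure-mode proportions are reported alongside; together with the
#' success rate they sum to 1.
#'
#' @param trials A trials tibble with an outcome column.
#' @param cue Reward cue label to summarise.
#' @param n_boot Number of bootstrap resamples (default 10,000).
#' @param seed Integer seed for the resampling.
#' @param outcome_col Name of the outcome column (default `outcome_final`,
#'   falling back to `outcome` or `truth_label` if absent).
#' @return A one-row tibble: `cue`, `n_trials`, `n_success`, `success_rate`,
#'   `bootstrap_se`, plus one `prop_<mode>` column per failure mode present.
#' @export
condition_stats <- function(trials, cue, n_boot = 10000, seed = 1,
                            outcome_col = NULL) {
  col <- resolve_outcome_col(trials, outcome_col)
  labs <- trials[[col]][trials$reward_cue == cue]
  if (!length(labs)) abort(sprintf("no trials with cue '%s'", cue))
  n <- length(labs)
  succ <- labs == "success"
  rate <- mean(succ)
  se <- if (n_boot > 0) {
    boot <- with_seed(seed, {
      matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    })
    sd(rowMeans(matrix(succ[boot], nrow = n_boot)))
  } else {
    NA_real_
  }
  props <- table(factor(labs, levels = outcome_labels())) / n
  fail_props <- props[setdiff(names(props), "success")]
  out <- tibble(cue = cue, n_trials = n, n_success = sum(succ),
                success_rate = rate, bootstrap_se = se)
  for (m in names(fail_props)) out[[paste0("prop_", m)]] <- as.double(fail_props[[m]])
  out
}

resolve_outcome_col <- function(trials, outcome_col = NULL) {
  if (!is.null(outcome_col)) {
    if (!outcome_col %in% names(trials)) {
      abort(sprintf("no column '%s' in trials", outcome_col))
    }
    return(outcome_col)
  }
  for (cand in c("outcome_final", "outcome", "truth_label")) {
    if (cand %in% names(trials)) return(cand)
  }
  abort("trials has no outcome column (outcome_final/outcome/truth_label)")
}

star_level <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Two-sample binomial proportion z-test
#'
#' Two-sided z-test of equal success probabilities with pooled variance:
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with `p` the pooled rate, p
#' from the normal tail. The difference is also reported in percentage
#' points (`delta_pp = (p1 - p2) * 100`).
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return A one-row tibble: `delta_pp`, `statistic`, `p_value`,
#'   `test_name`, `stars`.
#' @export
binomial_proportion_test <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) abort("both groups need at least one trial")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    abort("successes must satisfy 0 <= k <= n")
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  tibble(delta_pp = (p1 - p2) * 100, statistic = z,
         p_value = 2 * pnorm(-abs(z)), test_name = "binomial_proportion_z",
         stars = star_level(2 * pnorm(-abs(z))))
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test (Welch-Satterthwaite degrees of freedom), used for
#' mean comparisons such as peak speed and ballistic endpoint distance.
#'
#' @param sample_a,sample_b Numeric samples (each >= 2 values).
#' @return A one-row tibble: `mean_a`, `mean_b`, `delta`, `statistic`, `df`,
#'   `p_value`, `test_name`, `stars`.
#' @export
welch_t <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    abort("each sample needs at least 2 finite values")
  }
  if (sd(sample_a) == 0 && sd(sample_b) == 0) {
    abort("both samples are constant; Welch's t is undefined")
  }
  ht <- t.test(sample_a, sample_b, var.equal = FALSE)
  tibble(mean_a = mean(sample_a), mean_b = mean(sample_b),
         delta = mean(sample_a) - mean(sample_b),
         statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, test_name = "welch_t",
         stars = star_level(ht$p.value))
}

#' Mann-Whitney U test with medians
#'
#' Two-sided rank-sum test with tie correction (normal approximation with
#' continuity correction), used for heavy-tailed metrics such as reaction
#' and homing times, reported together with the group medians.
#'
#' @param sample_a,sample_b Numeric samples (each >= 1 value).
#' @return A one-row tibble: `median_a`, `median_b`, `statistic` (U for
#'   sample_a), `p_value`, `test_name`, `stars`.
#' @export
mann_whitney <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (!length(sample_a) || !length(sample_b)) {
    abort("each sample needs at least 1 finite value")
  }
  ht <- suppressWarnings(wilcox.test(sample_a, sample_b, exact = FALSE,
                                     correct = TRUE))
  p <- ht$p.value
  if (is.nan(p)) p <- 1 # fully tied samples: zero rank variance, no evidence
  tibble(median_a = median(sample_a), median_b = median(sample_b),
         statistic = unname(ht$statistic), p_value = p,
         test_name = "mann_whitney_u", stars = star_level(p))
}

#' Reward-condition choking profile
#'
#' The central analysis: per-cue success statistics over pooled trials, the
#' configured pairwise two-proportion comparisons (Small vs Large and Large
#' vs Jackpot by default), and a choking flag — `TRUE` when the Large
#' success rate exceeds the Jackpot rate with the pairwise test significant
#' at `alpha`.
#'
#' @param trials A trials tibble with an outcome column.
#' @param ordering Cue ordering for the profile (increasing stake).
#' @param pairs List of `c(cue_a, cue_b)` pairs to compare; defaults to
#'   adjacent anchor comparisons `Small~Large` and `Large~Jackpot` (using the
#'   first/third/last cues of `ordering` when those labels are absent).
#' @param n_boot,seed Bootstrap settings for [condition_stats()].
#' @param alpha Significance level of the choking flag.
#' @param outcome_col Outcome column override, see [condition_stats()].
#' @return An object of class `choking_profile`: a list with `stats` (per
#'   cue), `comparisons`, `choking`, `alpha`, `ordering`.
#' @export
choking_profile <- function(trials, ordering = c("Small", "Medium", "Large",
                                                 "Jackpot"),
                            pairs = NULL, n_boot = 10000, seed = 1,
                            alpha = 0.05, outcome_col = NULL) {
  col <- resolve_outcome_col(trials, outcome_col)
  present <- unique(trials$reward_cue)
  missing_cues <- setdiff(ordering, present)
  if (length(missing_cues)) {
    abort(sprintf("cue(s) %s absent from data; cues present: %s",
                  paste(missing_cues, collapse = ", "),
                  paste(sort(present), collapse = ", ")))
  }
  if (is.null(pairs)) {
    lo <- ordering[1]
    hi <- ordering[length(ordering)]
    anchor <- if ("Large" %in% ordering) "Large" else ordering[length(ordering) - 1]
    pairs <- list(c(lo, anchor), c(anchor, hi))
  }
  stats_tbl <- dplyr::bind_rows(lapply(seq_along(ordering), function(i) {
    condition_stats(trials, ordering[i], n_boot = n_boot,
                    seed = derive_seed(seed, i), outcome_col = col)
  }))
  comparisons <- dplyr::bind_rows(lapply(pairs, function(pr) {
    a <- stats_tbl[stats_tbl$cue == pr[1], ]
    b <- stats_tbl[stats_tbl$cue == pr[2], ]
    if (!nrow(a) || !nrow(b)) {
      abort(sprintf("comparison pair (%s, %s) not in profile cues",
                    pr[1], pr[2]))
    }
    dplyr::bind_cols(tibble(cue_a = pr[1], cue_b = pr[2]),
                     binomial_proportion_test(a$n_success, a$n_trials,
                                              b$n_success, b$n_trials))
  }))
  choking <- FALSE
  lj <- comparisons[comparisons$cue_a == "Large" &
                      comparisons$cue_b == "Jackpot", ]
  if (nrow(lj)) {
    choking <- lj$delta_pp[1] > 0 && lj$p_value[1] < alpha
  }
  structure(list(stats = stats_tbl, comparisons = comparisons,
                 choking = choking, alpha = alpha, ordering = ordering),
            class = "choking_profile")
}

#' @export
print.choking_profile <- function(x, ...) {
  cat("<choking_profile>\n")
  print(as.data.frame(x$stats[, c("cue", "n_trials", "success_rate",
                                  "bootstrap_se")]), row.names = FALSE)
  cat("comparisons:\n")
  print(as.data.frame(x$comparisons[, c("cue_a", "cue_b", "delta_pp",
                                        "p_value", "stars")]),
        row.names = FALSE)
  cat(sprintf("choking flag (Large > Jackpot, alpha = %g): %s\n",
              x$alpha, x$choking))
  invisible(x)
}

#' Tidy a choking profile
#'
#' @param x A `choking_profile`.
#' @param ... Unused.
#' @return The pairwise-comparison tibble (one row per comparison).
#' @method tidy choking_profile
#' @export
tidy.choking_profile <- function(x, ...) x$comparisons

#' One-row summary of a choking profile
#'
#' @param x A `choking_profile`.
#' @param ... Unused.
#' @return A one-row tibble: total trials, best cue, the Large-to-Jackpot
#'   decrement in percentage points (if computed) and the choking flag.
#' @method glance choking_profile
#' @export
glance.choking_profile <- function(x, ...) {
  lj <- x$comparisons[x$comparisons$cue_a == "Large" &
                        x$comparisons$cue_b == "Jackpot", ]
  tibble(
    n_trials = sum(x$stats$n_trials),
    best_cue = x$stats$cue[which.max(x$stats$success_rate)],
    large_jackpot_drop_pp = if (nrow(lj)) lj$delta_pp[1] else NA_real_,
    large_jackpot_p = if (nrow(lj)) lj$p_value[1] else NA_real_,
    choking = x$choking
  )
}

#' Per-session and per-subject choking counts
#'
#' A session counts as choking when its Jackpot success rate is below its
#' Large success rate (a point decrement; equal rates do not count). The
#' per-session two-proportion p-value is reported alongside, and a
#' significance-based count (`n_choking_sig`) is also returned, since
#' per-session Jackpot counts are small.
#'
#' @param trials A trials tibble with an outcome column spanning >= 1
#'   session.
#' @param cue_large,cue_jackpot The cue labels compared.
#' @param alpha Significance level for the significance-based count.
#' @param outcome_col Outcome column override.
#' @return A list with `sessions` (per-session rates, decrement, p-value)
#'   and `subjects` (`n_choking`, `n_choking_sig`, `n_sessions`,
#'   `n_excluded` per subject). Sessions lacking either cue are excluded and
#'   counted in `n_excluded`.
#' @export
session_choking_counts <- function(trials, cue_large = "Large",
                                   cue_jackpot = "Jackpot", alpha = 0.05,
                                   outcome_col = NULL) {
  col <- resolve_outcome_col(trials, outcome_col)
  per <- trials |>
    filter(.data$reward_cue %in% c(cue_large, cue_jackpot)) |>
    group_by(.data$subject_id, .data$session_id, .data$reward_cue) |>
    summarise(n = n(), k = sum(.data[[col]] == "success"), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "reward_cue",
                       values_from = c("n", "k"), values_fill = 0L)
  nL <- paste0("n_", cue_large); kL <- paste0("k_", cue_large)
  nJ <- paste0("n_", cue_jackpot); kJ <- paste0("k_", cue_jackpot)
  for (colname in c(nL, kL, nJ, kJ)) {
    if (!colname %in% names(per)) per[[colname]] <- 0L
  }
  complete <- per[[nL]] > 0 & per[[nJ]] > 0
  sessions <- per[complete, ] |>
    mutate(
      rate_large = .data[[kL]] / .data[[nL]],
      rate_jackpot = .data[[kJ]] / .data[[nJ]],
      decrement_pp = (.data$rate_large - .data$rate_jackpot) * 100,
      p_value = purrr::pmap_dbl(
        list(.data[[kL]], .data[[nL]], .data[[kJ]], .data[[nJ]]),
        function(k1, n1, k2, n2) {
          binomial_proportion_test(k1, n1, k2, n2)$p_value
        }),
      choking = .data$decrement_pp > 0,
      choking_sig = .data$choking & .data$p_value < alpha
    )
  excluded <- per[!complete, c("subject_id", "session_id")]
  subjects <- sessions |>
    group_by(.data$subject_id) |>
    summarise(n_choking = sum(.data$choking),
              n_choking_sig = sum(.data$choking_sig),
              n_sessions = n(), .groups = "drop") |>
    left_join(excluded |> dplyr::count(.data$subject_id, name = "n_excluded"),
              by = "subject_id") |>
    mutate(n_excluded = tidyr::replace_na(.data$n_excluded, 0L))
  list(sessions = sessions, subjects = subjects, excluded = excluded)
}

#' Decompose a success-rate change into failure-mode contributions
#'
#' For a pair of cues, each failure mode's contribution is its proportion
#' under `cue_b` minus under `cue_a`, in percentage points. Because outcome
#' proportions sum to 1 within each cue, the contributions sum exactly to
#' the negated success-rate change — e.g. a rise in undershoots from Large
#' to Jackpot accounts point-for-point for the success decrement.
#'
#' @param stats Per-cue stats tibble (the `stats` element of a
#'   [choking_profile()], or rows from [condition_stats()]).
#' @param cue_a,cue_b The cue pair (change measured from a to b).
#' @return A tibble with one row per failure mode: `mode`,
#'   `contribution_pp`, plus a `success_delta_pp` attribute-style column
#'   repeated for convenience.
#' @export
failure_mode_decomposition <- function(stats, cue_a, cue_b) {
  if (inherits(stats, "choking_profile")) stats <- stats$stats
  a <- stats[stats$cue == cue_a, ]
  b <- stats[stats$cue == cue_b, ]
  if (!nrow(a) || !nrow(b)) abort("both cues must be present in stats")
  prop_cols <- grep("^prop_", names(stats), value = TRUE)
  modes <- sub("^prop_", "", prop_cols)
  contrib <- vapply(prop_cols, function(cn) {
    pb <- if (cn %in% names(b)) b[[cn]][1] else 0
    pa <- if (cn %in% names(a)) a[[cn]][1] else 0
    (tidyr::replace_na(pb, 0) - tidyr::replace_na(pa, 0)) * 100
  }, numeric(1))
  tibble(cue_a = cue_a, cue_b = cue_b, mode = modes,
         contribution_pp = unname(contrib),
         success_delta_pp = (b$success_rate[1] - a$success_rate[1]) * 100)
}

#' Choice-task preference summary
#'
#' For each unordered pair of distinct cues presented in a two-target choice
#' task, the proportion of trials on which the higher-magnitude cue was
#' chosen; for equal-cue pairs, the proportion of rightward choices (side
#' bias).
#'
#' @param choices A tibble with columns `left_cue`, `right_cue`,
#'   `chosen_side` (`"left"`/`"right"`); optionally `subject_id`.
#' @param config A [task_config()] supplying cue magnitudes.
#' @return A tibble with one row per unordered cue pair: `cue_low`,
#'   `cue_high`, `n`, `prefer_higher` (or `side_bias_right` for equal
#'   pairs), and `overall_prefer_higher` repeated on each unequal-pair row.
#' @export
choice_preference <- function(choices, config) {
  if (!nrow(choices)) abort("no choice trials supplied")
  if (!all(choices$chosen_side %in% c("left", "right"))) {
    abort("chosen_side must be 'left' or 'right'")
  }
  mags <- stats::setNames(config$reward_cues$magnitude_ml,
                          config$reward_cues$cue)
  bad <- setdiff(unique(c(choices$left_cue, choices$right_cue)), names(mags))
  if (length(bad)) {
    abort(sprintf("unknown cue(s) in choices: %s", paste(bad, collapse = ", ")))
  }
  df <- choices |>
    mutate(
      mag_left = unname(mags[.data$left_cue]),
      mag_right = unname(mags[.data$right_cue]),
      cue_low = ifelse(.data$mag_left <= .data$mag_right, .data$left_cue,
                       .data$right_cue),
      cue_high = ifelse(.data$mag_left <= .data$mag_right, .data$right_cue,
                        .data$left_cue),
      equal = .data$mag_left == .data$mag_right,
      chose_higher = ifelse(.data$equal, NA,
                            (.data$chosen_side == "left") ==
                              (.data$mag_left > .data$mag_right)),
      chose_right = .data$chosen_side == "right"
    )
  overall <- mean(df$chose_higher[!df$equal])
  df |>
    group_by(.data$cue_low, .data$cue_high, .data$equal) |>
    summarise(n = n(),
              prefer_higher = mean(.data$chose_higher),
              side_bias_right = mean(.data$chose_right), .groups = "drop") |>
    mutate(prefer_higher = ifelse(.data$equal, NA_real_, .data$prefer_higher),
           side_bias_right = ifelse(.data$equal, .data$side_bias_right,
                                    NA_real_),
           overall_prefer_higher = ifelse(.data$equal, NA_real_, overall)) |>
    select(-"equal")
}
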