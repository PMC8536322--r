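label_trials <- function(labels, cue = "Large", session = "s1") {
  tibble::tibble(subject_id = "t", session_id = session,
                 trial_index = seq_along(labels), reward_cue = cue,
                 outcome_final = labels)
}

test_that("condition stats: rates, determinism, degenerate cases", {
  all_ok <- label_trials(rep("success", 10))
  st <- condition_stats(all_ok, "Large", n_boot = 2000, seed = 1)
  expect_equal(st$success_rate, 1)
  expect_equal(st$bootstrap_se, 0)

  half <- label_trials(rep(c("success", "undershoot"), 50))
  a <- condition_stats(half, "Large", n_boot = 3000, seed = 7)
  b <- condition_stats(half, "Large", n_boot = 3000, seed = 7)
  expect_identical(a$bootstrap_se, b$bootstrap_se)

  expect_error(condition_stats(half, "Jackpot"), "Jackpot")
})

test_that("bootstrap SE converges to the analytic binomial SE", {
  for (p in c(0.1, 0.5, 0.9)) {
    labs <- c(rep("success", round(100 * p)),
              rep("undershoot", 100 - round(100 * p)))
    st <- condition_stats(label_trials(labs), "Large", n_boot = 10000,
                          seed = 13)
    analytic <- sqrt(p * (1 - p) / 100)
    expect_lt(abs(st$bootstrap_se - analytic) / analytic, 0.1)
  }
})

test_that("two-proportion z-test: nulls, symmetry, and exact oracles", {
  eq <- binomial_proportion_test(30, 60, 50, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  r <- binomial_proportion_test(90, 100, 70, 100)
  fisher_p <- stats::fisher.test(matrix(c(90, 10, 70, 30), 2))$p.value
  expect_lt(r$p_value / fisher_p, 2)
  expect_gt(r$p_value / fisher_p, 0.5)
  exact_p <- exact_permutation_p(90, 100, 70, 100)
  expect_lt(r$p_value / exact_p, 2)
  expect_gt(r$p_value / exact_p, 0.5)
  # sampled permutation agrees with its exact enumeration
  perm <- with(list(), {
    set.seed(99)
    k1s <- stats::rhyper(1e5, 100, 100, 160)
    mean(abs(k1s / 100 - (160 - k1s) / 100) >= abs(0.9 - 0.7) - 1e-12)
  })
  expect_lt(abs(perm - exact_p), 3 * sqrt(exact_p * (1 - exact_p) / 1e5))

  sw <- binomial_proportion_test(70, 100, 90, 100)
  expect_equal(sw$p_value, r$p_value)
  expect_equal(sw$statistic, -r$statistic)
  expect_equal(sw$delta_pp, -20)
  expect_error(binomial_proportion_test(5, 0, 1, 10), "at least one")
})

test_that("Welch's t: identical samples, known effects, pooled-t limit", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  expect_equal(welch_t(x, x)$p_value, 1)

  set.seed(8)
  a <- rnorm(100)
  b <- rnorm(100, mean = 1)
  expect_lt(welch_t(a, b)$p_value, 1e-6)

  # equal n and equal variance: Welch reduces to the pooled t exactly
  b2 <- a + 0.3
  pooled <- stats::t.test(a, b2, var.equal = TRUE)$p.value
  expect_equal(welch_t(a, b2)$p_value, pooled, tolerance = 1e-6)

  expect_error(welch_t(rep(1, 5), rep(2, 5)), "constant")
})

test_that("Mann-Whitney U matches exhaustive pairwise enumeration", {
  x <- c(5, 5, 5)
  expect_gt(mann_whitney(x, x)$p_value, 0.9) # identity up to continuity corr.

  set.seed(12)
  for (rep in 1:50) {
    a <- sample(0:10, sample(2:8, 1), replace = TRUE)
    b <- sample(0:10, sample(2:8, 1), replace = TRUE)
    expect_equal(mann_whitney(a, b)$statistic, brute_force_u(a, b))
  }

  a <- rnorm(30)
  ps <- vapply(c(0.5, 1.5, 3), function(shift) {
    mann_whitney(a, a + shift)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("choking profile flags the Large-to-Jackpot decrement", {
  set.seed(31)
  labs <- c(rep("success", 950), rep("undershoot", 50))
  trials <- dplyr::bind_rows(
    label_trials(sample(labs), "Small"),
    label_trials(sample(labs), "Medium"),
    label_trials(sample(labs), "Large"),
    label_trials(sample(labs), "Jackpot"))
  pr <- choking_profile(trials, n_boot = 500, seed = 2)
  expect_false(pr$choking)
  expect_true(all(pr$stats$success_rate == 0.95))

  choked <- dplyr::bind_rows(
    label_trials(c(rep("success", 700), rep("overshoot", 300)), "Small"),
    label_trials(c(rep("success", 750), rep("overshoot", 250)), "Medium"),
    label_trials(c(rep("success", 850), rep("undershoot", 150)), "Large"),
    label_trials(c(rep("success", 120), rep("undershoot", 80)), "Jackpot"))
  pr2 <- choking_profile(choked, n_boot = 500, seed = 2)
  expect_true(pr2$choking)
  g <- glance(pr2)
  expect_identical(g$best_cue, "Large")
  expect_equal(g$large_jackpot_drop_pp, 25)
  expect_identical(tidy(pr2), pr2$comparisons)

  expect_error(choking_profile(trials[trials$reward_cue != "Jackpot", ]),
               "cues present")
})

test_that("all-success data yields flat rates, p = 1, no flag", {
  trials <- dplyr::bind_rows(lapply(c("Small", "Medium", "Large", "Jackpot"),
                                    function(cue) {
                                      label_trials(rep("success", 50), cue)
                                    }))
  pr <- choking_profile(trials, n_boot = 200, seed = 5)
  expect_true(all(pr$stats$success_rate == 1))
  expect_true(all(pr$comparisons$p_value == 1))
  expect_false(pr$choking)
})

test_that("session choking counts match a brute-force recount", {
  params <- preset_params("paper_like")
  sessions <- lapply(1:6, function(k) {
    generate_session(params, 600, seed = 500 + k, render = FALSE,
                     session_id = sprintf("s%02d", k))
  })
  trials <- dplyr::bind_rows(sessions)
  res <- session_choking_counts(trials, outcome_col = "truth_label")
  brute <- vapply(sessions, function(s) {
    rl <- mean(s$truth_label[s$reward_cue == "Large"] == "success")
    rj <- mean(s$truth_label[s$reward_cue == "Jackpot"] == "success")
    rj < rl
  }, logical(1))
  expect_equal(res$subjects$n_choking, sum(brute))
  expect_equal(res$subjects$n_sessions, 6)

  # ties do not count; sessions lacking a cue are excluded and reported
  tied <- dplyr::bind_rows(
    label_trials(rep(c("success", "undershoot"), 10), "Large", "tie"),
    label_trials(rep(c("success", "undershoot"), 5), "Jackpot", "tie"),
    label_trials(rep("success", 10), "Large", "nojack"))
  res2 <- session_choking_counts(tied, outcome_col = "outcome_final")
  expect_equal(res2$subjects$n_choking, 0)
  expect_equal(res2$subjects$n_excluded, 1)
})

test_that("failure-mode decomposition conserves the success delta", {
  st <- dplyr::bind_rows(
    condition_stats(label_trials(
      c(rep("success", 80), rep("undershoot", 10), rep("overshoot", 10)),
      "Large"), "Large", n_boot = 0),
    condition_stats(label_trials(
      c(rep("success", 70), rep("undershoot", 20), rep("overshoot", 10)),
      "Jackpot"), "Jackpot", n_boot = 0))
  dec <- failure_mode_decomposition(st, "Large", "Jackpot")
  expect_equal(sum(dec$contribution_pp), -dec$success_delta_pp[1],
               tolerance = 1e-9)
  expect_equal(dec$contribution_pp[dec$mode == "undershoot"], 10)
  expect_equal(dec$success_delta_pp[1], -10)

  same <- failure_mode_decomposition(dplyr::bind_rows(st[1, ], st[1, ] |>
                                                        dplyr::mutate(cue = "Jackpot")),
                                     "Large", "Jackpot")
  expect_true(all(same$contribution_pp == 0))
})

test_that("choice preferences summarise pairwise cue valuation", {
  cfg <- task_config()
  choices <- tibble::tibble(
    subject_id = "t",
    left_cue = c(rep("Jackpot", 10), rep("Small", 20), rep("Large", 10)),
    right_cue = c(rep("Small", 10), rep("Large", 20), rep("Large", 10)),
    chosen_side = c(rep("left", 10), # always Jackpot
                    rep("right", 19), "left", # 19/20 prefer Large
                    rep("right", 5), rep("left", 5)) # equal pair split
  )
  pref <- choice_preference(choices, cfg)
  jk <- pref[pref$cue_high == "Jackpot", ]
  expect_equal(jk$prefer_higher, 1)
  sl <- pref[pref$cue_low == "Small" & pref$cue_high == "Large", ]
  expect_equal(sl$prefer_higher, 0.95)
  eq <- pref[pref$cue_low == "Large" & pref$cue_high == "Large", ]
  expect_equal(eq$side_bias_right, 0.5)
})
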