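#' Success-rate curve across reward cues
#'
#' Points with bootstrap-SE error bars connected across the cue ordering;
#' an inverted-U with its maximum before the last cue is the signature of
#' choking under pressure.
#'
#' @param object A [choking_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot choking_profile
#' @export
autoplot.choking_profile <- function(object, ...) {
  df <- object$stats |>
    mutate(cue = factor(.data$cue, levels = object$ordering))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cue, y = .data$success_rate,
                                   group = 1)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$success_rate - .data$bootstrap_se,
      ymax = .data$success_rate + .data$bootstrap_se), width = 0.1) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "reward cue", y = "success rate",
                  title = "Success rate by reward") +
    ggplot2::theme_minimal()
}

#' Stacked outcome proportions by reward cue
#'
#' One bar per cue, stacked by outcome label (success plus each failure
#' mode). Shows at a glance which failure modes trade off across rewards.
#'
#' @param profile A [choking_profile()].
#' @return A ggplot object.
#' @export
plot_failure_modes <- function(profile) {
  stats <- profile$stats
  prop_cols <- grep("^prop_", names(stats), value = TRUE)
  df <- stats |>
    select("cue", "success_rate", dplyr::all_of(prop_cols)) |>
    dplyr::rename(prop_success = "success_rate") |>
    tidyr::pivot_longer(-"cue", names_to = "outcome", values_to = "prop",
                        names_prefix = "prop_") |>
    mutate(prop = tidyr::replace_na(.data$prop, 0),
           cue = factor(.data$cue, levels = profile$ordering),
           outcome = factor(.data$outcome,
                            levels = rev(c("success", setdiff(outcome_labels(),
                                                              "success")))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cue, y = .data$prop,
                                   fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "reward cue", y = "proportion of trials",
                  title = "Trial outcomes by reward") +
    ggplot2::theme_minimal()
}

#' Median kinematic metrics by reward cue
#'
#' Per-cue medians of a kinematic-summary column (e.g. homing time or
#' ballistic distance); undefined values are excluded and tallied in the
#' subtitle.
#'
#' @param metrics A [kinematic_summary()] tibble.
#' @param metric Column to summarise (default `"homing_time"`).
#' @param ordering Cue ordering.
#' @return A ggplot object.
#' @export
plot_kinematic_medians <- function(metrics, metric = "homing_time",
                                   ordering = c("Small", "Medium", "Large",
                                                "Jackpot")) {
  if (!metric %in% names(metrics)) {
    abort(sprintf("no column '%s' in metrics", metric))
  }
  n_undef <- sum(is.na(metrics[[metric]]))
  df <- metrics |>
    filter(!is.na(.data[[metric]]), .data$reward_cue %in% ordering) |>
    group_by(cue = factor(.data$reward_cue, levels = ordering)) |>
    summarise(value = median(.data[[metric]]), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cue, y = .data$value, group = 1)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "reward cue", y = sprintf("median %s", metric),
                  title = sprintf("Median %s by reward", metric),
                  subtitle = sprintf("%d undefined trial(s) excluded", n_undef)) +
    ggplot2::theme_minimal()
}
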