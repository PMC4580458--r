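# ggplot2 views of the main result types.

#' Plot a wait-time performance curve
#'
#' Dashed line: modelled performance (normalised expected discounted goal
#' occupancy) of waiting t bins before toggling; horizontal dotted line: the
#' optimal policy's value from the same context. If `empirical` is supplied
#' (an [empirical_wait_distribution()] tibble), its probabilities are drawn
#' as points on a secondary scale.
#'
#' @param object A `wait_curve` tibble from [wait_time_performance()].
#' @param empirical Optional empirical wait distribution tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wait_curve <- function(object, empirical = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$wait_bins, y = .data$performance)) +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::geom_hline(yintercept = attr(object, "optimal"), linetype = "dotted") +
    ggplot2::labs(x = "wait time (s)", y = "modelled performance",
                  title = sprintf("Goal: %s", object$goal[1])) +
    ggplot2::theme_minimal()
  if (!is.null(empirical) && nrow(empirical) > 0) {
    p <- p + ggplot2::geom_point(
      data = empirical,
      ggplot2::aes(x = .data$wait_bins, y = .data$prob),
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot mean goal posteriors across a cohort
#'
#' Bar chart of the across-dyad mean posterior per goal with 95% confidence
#' intervals of the mean.
#'
#' @param object A `goal_cohort` from [infer_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.goal_cohort <- function(object, ...) {
  m <- goal_means(object)
  m$goal <- factor(m$goal, levels = goal_levels())
  ggplot2::ggplot(m, ggplot2::aes(x = .data$goal, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey55") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                           width = 0.25) +
    ggplot2::geom_hline(yintercept = 0.25, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "mean posterior probability",
                  title = sprintf("Inferred goals (agent = %s)",
                                  attr(object, "agent_role") %||% "?")) +
    ggplot2::theme_minimal()
}

#' Plot the smile and gaze channels of a session
#'
#' @param object A [smile_series()] tibble.
#' @param ... Unused.
#' @return A ggplot raster of the three binary channels over time.
#' @export
autoplot.smile_series <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("infant_smile", "mother_smile", "gaze"),
                        names_to = "channel", values_to = "state")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$channel,
                                     fill = factor(.data$state))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey92", `1` = "grey25"),
                               name = "state") +
    ggplot2::labs(x = "time (bins)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot occupancy of the four smile configurations by controller
#'
#' @param object A [run_experiment()] tibble.
#' @param ... Unused.
#' @return A ggplot box plot of participant-only smiling seconds per
#'   controller condition.
#' @export
autoplot.smile_experiment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$condition <- factor(df$condition,
                         levels = c("infant", "replay", "mirror", "infant_plus"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$participant_only_s)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "controller", y = "participant-only smiling (s)") +
    ggplot2::theme_minimal()
}
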