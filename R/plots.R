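#' Plot a dF/F0 trace with detection thresholds
#'
#' @param dff A dF/F0 tibble (one or more larvae; larvae are faceted).
#' @param thresholds_pct Horizontal reference lines (percent dF/F0);
#'   defaults to the 5/10% event tiers and the 100% seizure level.
#' @return A ggplot object.
#' @export
plot_dff <- function(dff, thresholds_pct = c(5, 10, 100)) {
  check_recording_cols(dff, "dff_pct")
  ggplot2::ggplot(dff, ggplot2::aes(x = .data$time_s, y = .data$dff_pct)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = thresholds_pct, linetype = "dashed",
                        colour = "grey50", linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$larva_id), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = expression(Delta * F / F[0] ~ "(%)")) +
    ggplot2::theme_minimal()
}

#' Averaged seizure waveform with SEM ribbon
#'
#' The published-style overlay: per-timepoint mean of the aligned
#' seizures with a shaded standard-error band, time zero at the
#' alignment point (50% of maximum by default).
#'
#' @param object An `aligned_seizures` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aligned_seizures <- function(object, ...) {
  d <- tibble(time_s = object$time_s, mean = object$mean_trace,
              sem = object$sem_trace)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time from alignment point (s)",
      y = expression(Delta * F / F[0] ~ "(%)"),
      title = sprintf("Mean of %d aligned seizures (shading: SEM)",
                      object$n_traces)
    ) +
    ggplot2::theme_minimal()
}

#' Per-larva summary measure by group
#'
#' Box-and-jitter plot of one per-larva summary column (count, mean
#' amplitude, mean duration or AUC) by group and tier.
#'
#' @param summaries Output of [summarize_larvae()].
#' @param measure Column (tidy-eval) to plot, e.g. `event_count`.
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summaries, measure) {
  measure <- enquo(measure)
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$group, y = !!measure)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$tier), scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = as_name(measure)) +
    ggplot2::theme_minimal()
}
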