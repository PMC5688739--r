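#' Raster-style actogram of binned activity
#'
#' One row per day (calendar days, single-plotted by default; set
#' `double_plot = TRUE` for the traditional two-day-wide layout), tile
#' intensity proportional to the per-bin count.
#'
#' @param binned a [bin_activity()] table (one animal or several; counts
#'   are averaged per cell across animals).
#' @param double_plot repeat each day next to the following one.
#' @return a ggplot.
#' @export
plot_actogram <- function(binned, double_plot = FALSE) {
  df <- binned %>%
    group_by(.data$day, .data$hour) %>%
    summarise(count = mean(.data$count), .groups = "drop")
  if (double_plot) {
    nxt <- df %>% mutate(day = .data$day - 1, hour = .data$hour + 24) %>%
      filter(.data$day >= 1)
    df <- bind_rows(df, nxt)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour + (24 / max(1, length(unique(df$hour)))) / 2,
                                   y = .data$day, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = unique(df$day)) +
    ggplot2::scale_fill_gradient(low = "white", high = "black") +
    ggplot2::labs(x = "Clock time (h)", y = "Day", fill = "Counts") +
    ggplot2::theme_minimal()
}

#' Overlaid group actograms with SEM ribbons
#'
#' @param ... named `group_actogram` tables (names become group labels).
#' @return a ggplot of mean activity over the experiment with SEM bands.
#' @export
plot_group_actogram <- function(...) {
  groups <- list(...)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  df <- bind_rows(lapply(groups, as_tibble), .id = "group") %>%
    mutate(time_h = .data$bin_start_s / 3600)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$mean,
                                   color = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "Activity (counts/bin)",
                  color = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Interval histogram plot
#'
#' @param x interval series (see [event_intervals()]).
#' @param bin_width histogram bin width in seconds.
#' @return a ggplot.
#' @export
plot_interval_histogram <- function(x, bin_width = 0.1) {
  h <- interval_histogram(x, bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = bin_width) +
    ggplot2::labs(x = "Interval (s)", y = "Count") +
    ggplot2::theme_minimal()
}

#' Light-cycle modulation plot
#'
#' Per-transition percent modulation (activity after a light change
#' relative to before it); the 100% line marks the no-response level.
#'
#' @param modulation a [light_modulation()] table, optionally with an
#'   `animal_id` column.
#' @return a ggplot.
#' @export
plot_modulation <- function(modulation) {
  df <- modulation %>% filter(!is.na(.data$modulation_pct))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h / 24 + 1,
                                        y = .data$modulation_pct))
  if ("animal_id" %in% names(df)) {
    p <- p + ggplot2::aes(color = .data$animal_id)
  }
  p +
    ggplot2::geom_hline(yintercept = 100, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Day", y = "Modulation (%)", color = NULL) +
    ggplot2::theme_minimal()
}
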