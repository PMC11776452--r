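# ggplot2 displays for the main result types.

#' Plot a sliding-window synchrony series
#'
#' @param object A `sync_series` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sync_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window_center_s,
                                       y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "window center (s)",
                  y = attr(object, "measure") %||% "synchrony",
                  title = attr(object, "measure")) +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution with the observed statistic
#'
#' @param object A `perm_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perm_test <- function(object, ...) {
  d <- tibble::tibble(null = object$null_stats)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_stat,
                        colour = "#d7301f", linewidth = 1) +
    ggplot2::labs(x = "one-sample t (circularly shifted data)", y = "count",
                  title = sprintf("%s: p = %.4f", object$measure,
                                  object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot epoched synchrony (or rate) around section boundaries
#'
#' Mean ± standard error per 6-s window, split by condition when present —
#' the boundary-response display.
#'
#' @param epochs An `epoch_table` from [epoch_around_boundaries()].
#' @return A ggplot.
#' @export
plot_epochs <- function(epochs) {
  has_cond <- "condition" %in% names(epochs)
  grp <- c("window", if (has_cond) "condition",
           if ("measure" %in% names(epochs)) "measure")
  d <- dplyr::summarise(
    epochs,
    mean = mean(.data$value, na.rm = TRUE),
    se = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
    .by = dplyr::all_of(grp)
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$window, y = .data$mean,
                                       group = if (has_cond) .data$condition else 1)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se,
                                      fill = if (has_cond) .data$condition else NULL),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(colour = if (has_cond) .data$condition else NULL),
                       linewidth = 1) +
    ggplot2::labs(x = "window relative to boundary (s)", y = "mean value",
                  colour = "condition", fill = "condition") +
    ggplot2::theme_minimal()
  if ("measure" %in% names(epochs)) {
    p <- p + ggplot2::facet_wrap(~measure, scales = "free_y")
  }
  p
}

#' Plot the heart/respiration rate profile around boundaries
#'
#' @param profile A `rate_profile` from [boundary_rate_profile()].
#' @return A ggplot.
#' @export
plot_rate_profile <- function(profile) {
  d <- profile$window_means
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window, y = .data$mean_bpm,
                                  group = 1)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_bpm - .data$se_bpm,
                                      ymax = .data$mean_bpm + .data$se_bpm),
                         fill = "grey75", alpha = 0.5) +
    ggplot2::geom_line(colour = "#d7301f", linewidth = 1) +
    ggplot2::labs(x = "window relative to boundary (s)", y = "BPM") +
    ggplot2::theme_minimal()
}
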