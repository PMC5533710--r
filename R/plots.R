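#' Plot a recording's channels
#'
#' @param object A `gcg_recording`.
#' @param from,to Optional time window in seconds.
#' @param channels Channels to show (default: all).
#' @param ... Unused.
#' @return A ggplot object, channels stacked in facets.
#' @export
autoplot.gcg_recording <- function(object, from = NULL, to = NULL,
                                   channels = NULL, ...) {
  df <- as_tibble(unclass(object))
  if (!is.null(from)) df <- df %>% filter(.data$t >= from)
  if (!is.null(to)) df <- df %>% filter(.data$t <= to)
  channels <- channels %||% setdiff(names(df), "t")
  long <- tidyr::pivot_longer(df[c("t", channels)], -"t",
                              names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = channels)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel),
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble-averaged beat
#'
#' Mean waveform with a +/- 1 SD ribbon per channel.
#'
#' @param object A `gcg_ensemble` from [ensemble_average()].
#' @param channels Channels to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gcg_ensemble <- function(object, channels = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(channels)) df <- df %>% filter(.data$channel %in% channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_offset, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel),
                        scales = "free_y") +
    ggplot2::labs(x = "time from anchor (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Scatter of per-pair means against differences with the bias and 95%
#' limit-of-agreement lines.
#'
#' @param object A `gcg_bland_altman` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gcg_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "red") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "mean of methods", y = "difference") +
    ggplot2::theme_minimal()
}
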