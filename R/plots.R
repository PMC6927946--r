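# Quick-look figures (ggplot2, suggested dependency).

#' Plot a windowed learning curve
#'
#' @param series A [performance_series()] data frame.
#' @param metric `"fraction_correct"` or `"dprime"`.
#' @param threshold Optional criterion line (0.95 or 3, say).
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(series, metric = "fraction_correct",
                                threshold = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$trial,
                                            y = .data[[metric]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "completed trial", y = metric) +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  p
}

#' Plot a circadian activity histogram
#'
#' Hourly fraction of daily trials; the 18:00-06:00 dark phase is shaded.
#'
#' @param profile A [circadian_profile()] result.
#' @return A ggplot object.
#' @export
plot_circadian <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- data.frame(hour = 0:23, fraction = profile$hourly_fraction)
  dark <- data.frame(xmin = c(-0.5, 17.5), xmax = c(5.5, 23.5))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(data = dark,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
                       ymin = -Inf, ymax = Inf, fill = "grey85") +
    ggplot2::geom_col(ggplot2::aes(x = .data$hour, y = .data$fraction)) +
    ggplot2::labs(x = "hour of day", y = "fraction of daily trials",
                  title = profile$animal_id) +
    ggplot2::theme_minimal()
}
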