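sentiment_fill <- c(negative = "#c0504d", neutral = "#9a9a9a",
                    positive = "#4f81bd")

#' Plot the daily comment volume with stage shading
#'
#' @param volume Tibble `date`, `n` from [daily_volume()] (or a scored /
#'   comment tibble, from which the volume is computed).
#' @param plan Optional [segment_stages()] plan drawn as shaded bands.
#' @return A ggplot object.
#' @export
plot_daily_volume <- function(volume, plan = NULL) {
  if (!"date" %in% names(volume)) volume <- daily_volume(volume)
  p <- ggplot2::ggplot(volume, ggplot2::aes(x = .data$date, y = .data$n))
  if (!is.null(plan)) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(plan),
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                   fill = .data$label),
      inherit.aes = FALSE, alpha = 0.15
    ) + ggplot2::labs(fill = "stage")
  }
  p +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = "comments per day",
                  title = "Daily comment volume") +
    ggplot2::theme_minimal()
}

#' Plot per-stage emotion composition
#'
#' Stacked proportions of negative/neutral/positive comments per stage.
#'
#' @param object A [stage_summary()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stage_summary <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("label", "prop_negative", "prop_neutral", "prop_positive") |>
    tidyr::pivot_longer(-"label", names_to = "emotion", names_prefix = "prop_",
                        values_to = "proportion")
  long$emotion <- factor(long$emotion,
                         levels = c("negative", "neutral", "positive"))
  long$label <- factor(long$label, levels = object$label)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$proportion,
                                     fill = .data$emotion)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = sentiment_fill) +
    ggplot2::labs(x = NULL, y = "proportion of comments",
                  title = "Emotion composition by stage") +
    ggplot2::theme_minimal()
}

#' Plot regional audience shares
#'
#' @param object A [region_aggregate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_summary <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$region <- factor(dat$region, levels = rev(dat$region))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$share_all, y = .data$region)) +
    ggplot2::geom_col(fill = "#4f81bd") +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "share of all users", y = NULL,
                  title = "Audience by macro-region") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of comment sentiment values
#'
#' Histogram of total comment values E, coloured by sign label.
#'
#' @param scored A [score_comments()] result.
#' @param binwidth Histogram bin width (default 1).
#' @return A ggplot object.
#' @export
plot_sentiment_distribution <- function(scored, binwidth = 1) {
  ggplot2::ggplot(scored, ggplot2::aes(x = .data$E, fill = .data$label)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::scale_fill_manual(values = sentiment_fill) +
    ggplot2::labs(x = "comment sentiment value E", y = "comments",
                  title = "Sentiment value distribution") +
    ggplot2::theme_minimal()
}
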