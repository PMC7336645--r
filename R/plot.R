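#' Dot plot of grouped values with mean +/- SD bars
#'
#' The scatter-plot convention used for per-cell motility statistics:
#' one dot per observation, a bar at the group mean and whiskers at one
#' standard deviation. Requires ggplot2.
#'
#' @param values numeric vector (e.g. per-track mean speeds).
#' @param group group labels.
#' @param ylab y-axis label.
#' @return a ggplot object.
#' @export
plot_group_dots <- function(values, group, ylab = "value") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- data.frame(value = values, group = factor(group, levels = unique(group)))
  sm <- group_summary(values, group)
  sm$group <- factor(sm$group, levels = levels(df$group))
  ggplot2::ggplot(df, ggplot2::aes(x = group, y = value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::geom_crossbar(data = sm,
                           ggplot2::aes(y = mean, ymin = mean, ymax = mean),
                           width = 0.4, linewidth = 0.4) +
    ggplot2::geom_errorbar(data = sm,
                           ggplot2::aes(y = mean, ymin = mean - sd,
                                        ymax = mean + sd),
                           width = 0.2, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_classic()
}

utils::globalVariables(c("group", "value", "sd"))
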