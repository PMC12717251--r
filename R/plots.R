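#' Plot per-run metrics with t-distribution intervals
#'
#' Summarizes a metrics table (from [evaluate_predictions()]) as mean
#' points with t-interval error bars across repeated runs, faceted by
#' averaging mode.
#'
#' @param metrics tibble from [evaluate_predictions()].
#' @param metric which metric column to display.
#' @param level interval level for the across-run t interval.
#' @return a ggplot object.
#' @export
plot_metrics <- function(metrics, metric = "f1", level = 0.95) {
  summ <- metrics |>
    dplyr::group_by(.data$source, .data$mode, .data$strict) |>
    dplyr::summarise(t_interval(.data[[metric]], level = level),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$source, y = .data$mean,
                                     colour = .data$strict)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      width = 0.2, position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(y = metric, x = NULL, colour = "strict") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot stratified metrics
#'
#' @param strat tibble from [stratified_metrics()] (or [pipeline_stratify()]).
#' @param metric which metric column to display.
#' @return a ggplot object; one panel per stratification scheme.
#' @export
plot_strata <- function(strat, metric = "f1") {
  strat <- strat[!is.na(strat[[metric]]), , drop = FALSE]
  ggplot2::ggplot(strat, ggplot2::aes(x = .data$stratum,
                                      y = .data[[metric]],
                                      colour = .data$source)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~scheme, scales = "free_x") +
    ggplot2::labs(x = NULL, y = metric, colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the bootstrap difference distribution
#'
#' Histogram of the bootstrap metric differences (B minus A) with the
#' percentile interval and zero reference.
#'
#' @param object a `boot_compare` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot boot_compare
#' @export
autoplot.boot_compare <- function(object, ...) {
  df <- tibble::tibble(diff = object$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diff)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        colour = "steelblue") +
    ggplot2::labs(
      x = sprintf("bootstrap %s %s difference (B - A)",
                  object$mode, object$metric),
      y = "iterations",
      subtitle = sprintf("mean diff %.3f, p = %.4g (side = %s)",
                         object$mean_diff, object$p, object$side)) +
    ggplot2::theme_minimal()
}
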