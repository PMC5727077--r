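#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of the log varRatio distribution
#'
#' Mirrors the supplementary-style histogram used to pick the extreme lists:
#' log varRatio across pairs with dashed lines at the mean +- k sd thresholds
#' (when [select_var_extremes()] has been applied).
#'
#' @param object A `natpairs_varratio` tibble.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot natpairs_varratio
#' @export
autoplot.natpairs_varratio <- function(object, bins = 60, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$log_var_ratio)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::labs(
      x = "log varRatio (tumor NAT/PC ratio over normal NAT/PC ratio)",
      y = "pairs"
    ) +
    ggplot2::theme_minimal()
  lo <- attr(object, "threshold_low")
  hi <- attr(object, "threshold_high")
  if (!is.null(lo) && !is.null(hi)) {
    p <- p + ggplot2::geom_vline(xintercept = c(lo, hi), linetype = "dashed")
  }
  p
}

#' Bar chart of differential-correlation class proportions
#'
#' @param object A `natpairs_diffcor` tibble.
#' @param drop_concordant_null Drop the dominant `0/0` bin to make the other
#'   classes visible (default `FALSE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot natpairs_diffcor
#' @export
autoplot.natpairs_diffcor <- function(object, drop_concordant_null = FALSE,
                                      ...) {
  d <- summarize_diffcor_classes(object)
  if (drop_concordant_null) d <- filter(d, .data$diffcor_class != "0/0")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$diffcor_class, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "correlation class (normal/tumor)", y = "pairs") +
    ggplot2::theme_minimal()
}
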