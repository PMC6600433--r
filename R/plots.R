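#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' SAM observed-vs-expected plot
#'
#' The classic quantile-quantile style SAM plot: observed ordered d against
#' the permutation-expected order statistic, with the identity line, the
#' calling band at the selected delta, and called probes highlighted.
#'
#' @param x A [sam_call()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sam_result
#' @export
autoplot.sam_result <- function(x, ...) {
  dat <- arrange(x$stats, .data$d)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$dbar, y = .data$d)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = c(-x$delta, x$delta),
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$called), size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::labs(x = "expected order statistic",
                  y = "observed relative difference d",
                  colour = "called",
                  title = sprintf("SAM: delta = %.3g, est. FDR = %.3g",
                                  x$delta, x$fdr_at_delta)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sam_result
#' @export
plot_sam <- function(x, ...) autoplot.sam_result(x, ...)

#' Bar chart of concordant-record counts
#'
#' @param x A [summarize_sets()] result.
#' @param ... Unused.
#' @return A ggplot object showing record counts per compartment and cell
#'   type, split by direction.
#' @method autoplot concord_summary
#' @export
autoplot.concord_summary <- function(x, ...) {
  dat <- x$records %>%
    count(.data$compartment, .data$cell_type, .data$direction)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cell_type, y = .data$n,
                                    fill = .data$direction)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~compartment) +
    ggplot2::labs(x = NULL, y = "concordant records", fill = "direction") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.concord_summary
#' @export
plot_concordance <- function(x, ...) autoplot.concord_summary(x, ...)
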