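# ggplot2 views of the pipeline's result types

#' Plot sliding-window read profiles
#'
#' One panel per donor chromosome showing the donor-origin read count along
#' the window grid — the visual signature of a whole added chromosome is a
#' continuous band of high counts. Called chromosomes are highlighted when a
#' report is supplied.
#'
#' @param profiles Window profile tibble from [window_counts()].
#' @param report Optional `alien_call_report` used to colour present
#'   chromosomes.
#' @return A ggplot object.
#' @export
plot_window_profile <- function(profiles, report = NULL) {
  d <- profiles
  if (!is.null(report)) {
    calls <- tibble(chrom = report$chrom, present = report$present)
    d <- left_join(d, calls, by = "chrom")
  } else {
    d$present <- FALSE
  }
  ggplot2::ggplot(d, ggplot2::aes(x = window_start / 1e6, y = count,
                                  colour = present)) +
    ggplot2::geom_step(linewidth = 0.3, show.legend = !is.null(report)) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 name = "called present") +
    ggplot2::labs(x = "window start (Mb)",
                  y = "donor-origin reads per window") +
    ggplot2::theme_minimal(base_size = 9)
}

#' @method autoplot alien_call_report
#' @export
autoplot.alien_call_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = chrom, y = fraction_supported,
                                  fill = present)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "params")$min_window_frac,
                        linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "fraction of supported windows") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the identity distribution of alignment segments
#'
#' Histogram of per-segment identity, span-weighted (total aligned bp per
#' identity bin).
#'
#' @param dist Result of [identity_distribution()].
#' @return A ggplot object.
#' @export
plot_identity_distribution <- function(dist) {
  d <- dist$histogram
  d <- d[d$n_segments > 0 | d$total_span > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = (bin_low + bin_high) / 2,
                                  y = total_span / 1e6)) +
    ggplot2::geom_col(width = d$bin_high[1] - d$bin_low[1],
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = dist$weighted_median_identity,
                        linetype = 2) +
    ggplot2::labs(x = "percent identity", y = "aligned span (Mb)") +
    ggplot2::theme_minimal(base_size = 9)
}

utils::globalVariables(c("bin_low", "bin_high", "total_span"))
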