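# ggplot2 front-ends for the main result types. Numeric summaries are the
# tested surface; these functions only arrange them on the page.

#' MA plot of a calibrated DE fit
#'
#' @param object A `calq_de` object.
#' @param ... Ignored.
#' @return A ggplot: mean expression vs shrunken log2 fold change, points
#'   colored by significance class.
#' @export
autoplot.calq_de <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$baseMean,
                                   y = .data$lfc_shrunk,
                                   color = .data$sig_class)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6, na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_color_manual(
      values = c(up = "#b2182b", down = "#2166ac", no_change = "grey60")) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "mean normalized counts",
                  y = "log2 fold change (shrunken)", color = NULL)
}

#' Box plot of per-state fold changes
#'
#' Draws the per-state quartile boxes with 1.5 x IQR whiskers and the
#' intergenic-median baseline as a dashed line.
#'
#' @param x A `calq_state_lfc` object from [state_fold_changes()].
#' @return A ggplot.
#' @export
plot_state_lfc <- function(x) {
  s <- x$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$state)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_lo, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_hi),
      stat = "identity", width = 0.6) +
    ggplot2::geom_hline(yintercept = x$baseline, linetype = "dashed",
                        color = "grey40") +
    ggplot2::labs(x = NULL, y = "log2 fold change (B / A)")
}

#' Meta-profile line plot
#'
#' @param profile Output of [metaprofile()] (optionally several, row-bound
#'   with a `group` column).
#' @return A ggplot of signal vs distance from the anchor center.
#' @export
plot_metaprofile <- function(profile) {
  aes <- if ("group" %in% names(profile)) {
    ggplot2::aes(x = .data$offset, y = .data$value, color = .data$group)
  } else {
    ggplot2::aes(x = .data$offset, y = .data$value)
  }
  ggplot2::ggplot(profile, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from anchor center (bp)",
                  y = "signal")
}

#' Chromosome density plot of binned counts
#'
#' @param bins Output of [binned_coverage()] (optionally with a `sample`
#'   column for faceting).
#' @return A ggplot of per-bin counts along each chromosome.
#' @export
plot_chromosome_density <- function(bins) {
  p <- ggplot2::ggplot(bins, ggplot2::aes(x = .data$start / 1e6,
                                          y = .data$count)) +
    ggplot2::geom_col(width = diff(range(bins$start)) / nrow(bins) / 1e6) +
    ggplot2::labs(x = "position (Mb)", y = "fragments per bin")
  facets <- intersect(c("chrom", "sample"), names(bins))
  p + ggplot2::facet_grid(
    stats::reformulate(facets[1],
                       if (length(facets) > 1) facets[2] else "."))
}
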