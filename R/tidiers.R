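# broom-style accessors for fitted objects.

#' Tidy a calibrated DE fit
#'
#' @param x A `calq_de` object.
#' @param ... Ignored.
#' @return The per-gene results tibble.
#' @export
tidy.calq_de <- function(x, ...) {
  x$results
}

#' One-row summary of a calibrated DE fit
#'
#' @param x A `calq_de` object.
#' @param ... Ignored.
#' @return One-row tibble: gene counts by class, number tested, expression
#'   threshold and thresholds used.
#' @export
glance.calq_de <- function(x, ...) {
  r <- x$results
  tibble::tibble(
    n_genes = nrow(r),
    n_tested = sum(!is.na(r$p)),
    n_up = sum(r$sig_class == "up"),
    n_down = sum(r$sig_class == "down"),
    n_expressed = if ("expressed" %in% names(r)) sum(r$expressed)
                  else NA_integer_,
    rpkm_threshold = x$params$rpkm_threshold,
    padj_threshold = x$params$padj_threshold,
    fc_threshold = x$params$fc_threshold,
    size_factor_source = x$params$size_factor_source
  )
}

#' Tidy per-state fold-change summaries
#'
#' @param x A `calq_state_lfc` object.
#' @param ... Ignored.
#' @return The per-state summary tibble with the baseline attached as a
#'   column.
#' @export
tidy.calq_state_lfc <- function(x, ...) {
  dplyr::mutate(x$summary, baseline = x$baseline)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
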