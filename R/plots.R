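#' Plot a density grid with its cutoff
#'
#' Density curve of the splitter gene with local minima marked and the
#' chosen cutoff as a dashed vertical line.
#'
#' @param object An `evi1_cutoff` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evi1_cutoff <- function(object, ...) {
  g <- ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "log2 expression", y = "density",
                  title = sprintf("Expression density (rule: %s)",
                                  object$rule_applied))
  if (length(object$minima) > 0) {
    g <- g + ggplot2::geom_point(
      data = tibble::tibble(x = object$minima, density = object$minima_density),
      colour = "grey40"
    )
  }
  if (!is.na(object$cutoff)) {
    g <- g + ggplot2::geom_vline(xintercept = object$cutoff,
                                 linetype = "dashed", colour = "red")
  }
  g
}

#' Plot the resampled difference distribution
#'
#' Histogram of the per-iteration mean differences `d_i` with M marked;
#' the Z-score is `-M/SD` of this distribution.
#'
#' @param object An `evi1_bootstrap` object.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evi1_bootstrap <- function(object, bins = 50, ...) {
  ggplot2::ggplot(tibble::tibble(d = object$d), ggplot2::aes(x = .data$d)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$M, colour = "red") +
    ggplot2::labs(
      x = "mean difference (high - resampled low), log2",
      y = "iterations",
      title = sprintf("M = %.3f, SD = %.3f, Z = %.2f, p = %.2g",
                      object$M, object$SD, object$Z, object$p_two_sided)
    )
}

#' @rdname autoplot.evi1_cutoff
#' @export
autoplot.evi1_cohort_assoc <- function(object, ...) {
  autoplot(object$cutoff_result, ...)
}

#' Heatmap-style plot of regulated-gene fold changes
#'
#' Tile plot of per-time-point log2 fold changes for called genes, rows in
#' the descending 48 h order produced by [order_for_heatmap()].
#'
#' @param calls Gene-level calls from [regulated_genes()] /
#'   [order_for_heatmap()].
#' @return A ggplot object.
#' @export
plot_regulation_heatmap <- function(calls) {
  long <- calls |>
    dplyr::select("gene", dplyr::starts_with("fc_")) |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "log2fc") |>
    dplyr::mutate(
      sample = sub("^fc_", "", .data$sample),
      gene = factor(.data$gene, levels = rev(calls$gene))
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$gene,
                                     fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
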