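#' Volcano-style display of a differential occupancy test
#'
#' z-score against -log10 adjusted p, selected peaks highlighted.
#'
#' @param object An `occupancy_test` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.occupancy_test <- function(object, ...) {
  d <- tidy(object) |> filter(.data$status == "ok")
  ggplot2::ggplot(d, ggplot2::aes(.data$z, -log10(.data$padj),
                                  colour = .data$selected)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = sprintf("z (%s - %s)", object$condition_a, object$condition_b),
      y = "-log10 adjusted p", colour = sprintf("padj < %g", object$alpha)) +
    ggplot2::theme_minimal()
}

#' Violin display of per-cell QC metrics
#'
#' log(x + 1) distributions of reads-in-windows and non-zero peaks per
#' condition, the standard single-nucleus tagmentation QC view.
#'
#' @param qc A [cell_qc_report()] tibble (or the `qc` element of
#'   [build_matrix()]).
#' @return A ggplot.
#' @export
plot_cell_qc <- function(qc) {
  d <- qc |>
    tidyr::pivot_longer(c("total_reads_in_windows", "nonzero_peaks"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$condition, log1p(.data$value),
                                  fill = .data$condition)) +
    ggplot2::geom_violin(scale = "width") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "log(x + 1)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Scatter display of a 2-D cell embedding
#'
#' @param coords Tibble from [embed_cells()].
#' @return A ggplot coloured by condition.
#' @export
plot_embedding <- function(coords) {
  ggplot2::ggplot(coords, ggplot2::aes(.data$umap1, .data$umap2,
                                       colour = .data$condition)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bubble-matrix display of pathway occupancy results
#'
#' Colour encodes the mean log2 occupancy ratio, bubble size the -log10
#' paired-t p-value; pathways ordered by ratio.
#'
#' @param results Tibble from [pathway_occupancy()].
#' @return A ggplot.
#' @export
plot_pathway_occupancy <- function(results) {
  d <- results |> filter(!is.na(.data$t_stat)) |>
    mutate(pathway = stats::reorder(.data$pathway, .data$mean_log2_ratio))
  ggplot2::ggplot(d, ggplot2::aes(.data$factor, .data$pathway,
                                  size = .data$minus_log10_p,
                                  colour = .data$mean_log2_ratio)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, size = "-log10 p",
                  colour = "mean log2 ratio") +
    ggplot2::theme_minimal()
}
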