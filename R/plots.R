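#' Scatter plot of the LSI embedding
#'
#' @param x an `atac_clustering` result.
#' @param colour_by `"cluster"`, `"coarse"` or `"sample"`.
#' @return a ggplot.
#' @export
plot_embedding <- function(x, colour_by = c("cluster", "coarse", "sample")) {
  colour_by <- match.arg(colour_by)
  df <- tidy.atac_clustering(x) |>
    dplyr::filter(.data$retained) |>
    dplyr::mutate(colour = factor(.data[[colour_by]]))
  ggplot2::ggplot(df, ggplot2::aes(.data$lsi1, .data$lsi2,
                                   colour = .data$colour)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(x = "LSI 1", y = "LSI 2", colour = colour_by) +
    ggplot2::theme_minimal()
}

#' Stacked-bar plot of inferred cell-type compositions
#'
#' @param x a `decon_result` or its tidied composition tibble.
#' @return a ggplot.
#' @export
plot_composition <- function(x) {
  df <- if (inherits(x, "decon_result")) x$composition else x
  ggplot2::ggplot(df, ggplot2::aes(.data$bulk_sample, .data$composition,
                                   fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "bulk sample", y = "inferred composition",
                  fill = "cell type") +
    ggplot2::theme_minimal()
}

#' Residual curve of the NMF rank selection
#'
#' @param x a [select_rank()] result.
#' @return a ggplot with the chosen rank marked.
#' @export
plot_rank_selection <- function(x) {
  ggplot2::ggplot(x$residuals, ggplot2::aes(.data$rank, .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = x$rank, linetype = "dashed") +
    ggplot2::labs(x = "rank", y = "KL residual") +
    ggplot2::theme_minimal()
}

#' Activity-correlation versus PPI scatter of candidate core genes
#'
#' @param x a [core_gene_table()] result.
#' @return a ggplot, faceted by in-set membership, with top-PPI symbols
#'   highlighted.
#' @export
plot_core_genes <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(.data$correlation, .data$ppi_total,
                                  colour = .data$top_ppi)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~ifelse(.data$in_gs, "in gene set",
                                "not in gene set")) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red",
                                            `FALSE` = "blue")) +
    ggplot2::labs(x = "correlation with GS activity score",
                  y = "total PPI with the gene set", colour = "top 5% PPI") +
    ggplot2::theme_minimal()
}
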