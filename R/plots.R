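# ggplot2 displays for the main result types.

#' Dot plot of panel log fold changes by SCZ group
#'
#' One point per gene and group; filled points are significant (BH-adjusted
#' p < 0.05), hollow points are not — the panel figure style used for
#' neuroinflammation components.
#'
#' @param logfc_table Long tibble from [panel_logfc_table()].
#' @return A ggplot object.
#' @export
plot_panel_logfc <- function(logfc_table) {
  ggplot2::ggplot(logfc_table,
                  ggplot2::aes(x = .data$log2fc, y = .data$gene,
                               colour = .data$group, shape = .data$de_flag)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(size = 2.5, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "DE (padj < 0.05)") +
    ggplot2::labs(x = "log2 fold change vs controls", y = NULL, colour = "group") +
    ggplot2::theme_minimal()
}

#' Boxplot of one gene's expression across subject groups
#'
#' @param expr Expression matrix, typically [log2p1_expression()] output.
#' @param gene Gene to plot.
#' @param groups Named group labels (names = sample IDs).
#' @return A ggplot object.
#' @export
plot_gene_groups <- function(expr, gene, groups) {
  if (!gene %in% rownames(expr)) abort(sprintf("gene '%s' not in expression matrix", gene))
  common <- intersect(colnames(expr), names(groups))
  df <- tibble::tibble(group = factor(groups[common],
                                      levels = c("Control", "Type1", "Mix", "Type2")),
                       value = expr[gene, common])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value, fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, show.legend = FALSE) +
    ggplot2::labs(title = gene, x = NULL, y = "log2(normalized count + 1)") +
    ggplot2::theme_minimal()
}

#' Tile map of per-dataset subtype labels and the consensus
#'
#' @param consensus An `scz_consensus` from [consensus_classify()].
#' @return A ggplot object.
#' @export
plot_consensus <- function(consensus) {
  stopifnot(inherits(consensus, "scz_consensus"))
  ds <- attr(consensus, "datasets")
  long <- tidyr::pivot_longer(tibble::as_tibble(consensus),
                              cols = dplyr::all_of(c(ds, "consensus")),
                              names_to = "dataset", values_to = "label")
  ord <- consensus$subject_id[order(consensus$consensus)]
  long$subject_id <- factor(long$subject_id, levels = ord)
  long$dataset <- factor(long$dataset, levels = c(ds, "consensus"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dataset, y = .data$subject_id,
                                     fill = .data$label)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(Type1 = "#4daf4a", Type2 = "#984ea3",
                                          Mix = "#377eb8")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "shared case subjects", fill = "subtype")
}
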