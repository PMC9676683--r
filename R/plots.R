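# ggplot2 views of the main result types.

#' Volcano plot of a DE result
#'
#' @param object An `nbde_tbl`.
#' @param lfc_min,fdr Thresholds drawn and used for colouring.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nbde_tbl <- function(object, lfc_min = 1.5, fdr = 0.05, ...) {
  df <- as_tibble(object) |>
    mutate(status = dplyr::case_when(
      .data$padj <= fdr & .data$log2fc >= lfc_min ~ "up",
      .data$padj <= fdr & .data$log2fc <= -lfc_min ~ "down",
      TRUE ~ "ns"
    ))
  ggplot(df, aes(x = .data$log2fc, y = -log10(pmax(.data$padj, 1e-300)),
                 colour = .data$status)) +
    geom_point(size = 0.8, alpha = 0.7) +
    scale_colour_manual(values = c(up = "seagreen", down = "steelblue", ns = "grey70")) +
    geom_vline(xintercept = c(-lfc_min, lfc_min), linetype = 2, linewidth = 0.3) +
    labs(x = "log2 fold change", y = "-log10 adjusted p", colour = NULL) +
    theme_minimal()
}

#' Standardized expression profiles per cluster
#'
#' @param object An `expr_clusters` object.
#' @param ... Unused.
#' @return A ggplot of per-gene z-scored profiles, faceted by cluster label,
#'   with the medoid profile highlighted.
#' @export
autoplot.expr_clusters <- function(object, ...) {
  m <- object$matrix
  df <- as_tibble(m, rownames = "gene_id") |>
    inner_join(object$assignments, by = "gene_id") |>
    tidyr::pivot_longer(cols = colnames(m), names_to = "condition",
                        values_to = "z")
  df$condition <- factor(df$condition, levels = colnames(m))
  ggplot(df, aes(x = .data$condition, y = .data$z, group = .data$gene_id)) +
    geom_line(alpha = 0.15, colour = "grey40") +
    geom_line(data = filter(df, .data$gene_id %in% object$medoids),
              colour = "firebrick", linewidth = 0.9) +
    facet_wrap(~label) +
    labs(x = NULL, y = "z-scored mean expression") +
    theme_minimal()
}

#' Positional motif-frequency curves
#'
#' @param positional Output of [positional_distribution()].
#' @return A ggplot of fraction of peaks with a hit per offset bin.
#' @export
plot_positional_distribution <- function(positional) {
  ggplot(positional, aes(x = .data$bin_mid, y = .data$fraction, colour = .data$motif)) +
    geom_line() +
    labs(x = "offset from summit (bp)", y = "fraction of peaks", colour = NULL) +
    theme_minimal()
}

#' Smoothed distance-to-TSS curves by motif class and direction
#'
#' @param curves Output of [distance_direction_curve()].
#' @return A ggplot, faceted by motif class.
#' @export
plot_direction_curves <- function(curves) {
  ggplot(curves, aes(x = .data$x / 1000, y = .data$density, colour = .data$direction)) +
    geom_line() +
    facet_wrap(~motif_class, scales = "free_y") +
    scale_colour_manual(values = c(up = "seagreen", down = "steelblue",
                                   `non-DE` = "grey60")) +
    labs(x = "distance to TSS (kb)", y = "peak density", colour = NULL) +
    theme_minimal()
}

#' Motif-count histogram per peak group
#'
#' @param histogram Output of [motif_histogram()].
#' @return A ggplot of occurrence-class fractions per group.
#' @export
plot_motif_histogram <- function(histogram) {
  ggplot(histogram, aes(x = .data$bin, y = .data$fraction, fill = .data$group)) +
    geom_col(position = "dodge") +
    labs(x = "motif instances per peak", y = "fraction of peaks", fill = NULL) +
    theme_minimal()
}

#' Running-sum trace of an enrichment score
#'
#' @param es Output of [enrichment_score()].
#' @return A ggplot of the running sum with hit positions marked.
#' @export
plot_enrichment <- function(es) {
  df <- es$running
  ggplot(df, aes(x = .data$rank, y = .data$score)) +
    geom_line(colour = "seagreen") +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    geom_rug(data = df[es$hits, ], sides = "b") +
    labs(x = "rank", y = "running enrichment score") +
    theme_minimal()
}
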