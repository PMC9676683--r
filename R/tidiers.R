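# broom-style tidiers for the fitted objects.

#' @export
tidy.nbde_tbl <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @export
glance.nbde_tbl <- function(x, ...) {
  pair <- attr(x, "condition_pair")
  tibble(
    contrast = paste(pair, collapse = " vs "),
    n_genes = nrow(x),
    n_signif = sum(x$padj <= 0.05 & abs(x$log2fc) >= 1.5, na.rm = TRUE),
    n_all_zero = sum(x$all_zero),
    median_dispersion = median(x$dispersion[!x$all_zero]),
    df = attr(x, "df")
  )
}

#' @export
tidy.expr_clusters <- function(x, ...) x$assignments

#' @export
glance.expr_clusters <- function(x, ...) {
  tibble(k = x$k, n_genes = nrow(x$assignments),
         n_labels = dplyr::n_distinct(x$assignments$label),
         objective = x$objective, n_swaps = length(x$objective_trace) - 1L)
}

#' @export
tidy.gsea_results <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @export
glance.gsea_results <- function(x, ...) {
  tibble(n_sets = nrow(x), n_perm = x$n_perm[1],
         n_signif = sum(x$fdr_q < 0.05, na.rm = TRUE))
}
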