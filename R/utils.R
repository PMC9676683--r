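# Internal helpers shared across modules.

# Coordinates are 0-based half-open throughout ([start, end)); IRanges is
# 1-based closed, so conversion happens in exactly these two helpers.
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

from_iranges0 <- function(ir) {
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive", name))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Validate a peak table
#'
#' A peak table is a tibble with one ChIP-seq peak per row in 0-based
#' half-open coordinates and an absolute summit position. Columns beyond the
#' required set (e.g. `tf`, `condition`, `group`) pass through untouched.
#'
#' @param peaks A data frame with columns `chrom`, `start`, `end`, `name`,
#'   `summit` (absolute bp of the maximal-signal base).
#' @return The input as a tibble, invisibly validated.
#' @export
validate_peaks <- function(peaks) {
  assert_columns(peaks, c("chrom", "start", "end", "name", "summit"), "peak table")
  peaks <- as_tibble(peaks)
  bad <- which(!(peaks$start >= 0 & peaks$start < peaks$end))
  if (length(bad)) {
    abort(sprintf("peak row(s) %s violate 0 <= start < end",
                  paste(head(bad, 5), collapse = ", ")))
  }
  bad <- which(!(peaks$summit >= peaks$start & peaks$summit < peaks$end))
  if (length(bad)) {
    abort(sprintf("peak row(s) %s have summit outside [start, end)",
                  paste(head(bad, 5), collapse = ", ")))
  }
  peaks
}

#' Bundle gene models into a genome annotation
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`+`/`-`), in 0-based half-open coordinates. A `tss` column is
#'   derived if absent: `start` on `+`, `end - 1` on `-`.
#' @param exons Optional tibble of exons (`gene_id`, `chrom`, `start`, `end`).
#'   Defaults to one exon spanning each gene.
#' @param chrom_lengths Optional named vector of chromosome lengths (bp).
#' @return A `genome_annotation` object (list of tibbles).
#' @export
genome_annotation <- function(genes, exons = NULL, chrom_lengths = NULL) {
  assert_columns(genes, c("gene_id", "chrom", "start", "end", "strand"), "gene table")
  genes <- as_tibble(genes)
  if (anyDuplicated(genes$gene_id)) {
    abort(sprintf("duplicate gene id(s): %s",
                  paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'")
  }
  if (!all(genes$start < genes$end)) abort("gene start must be < end")
  if (!"tss" %in% names(genes)) {
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  }
  if (is.null(exons)) {
    exons <- genes[, c("gene_id", "chrom", "start", "end")]
  }
  exons <- assert_columns(as_tibble(exons), c("gene_id", "chrom", "start", "end"), "exon table")
  structure(
    list(genes = genes, exons = exons, chrom_lengths = chrom_lengths),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

#' @export
as_tibble.genome_annotation <- function(x, ...) x$genes

# Derive a reproducible child seed from a user seed and a stream label,
# staying below .Machine$integer.max.
child_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream)) %% 99991L
  (as.integer(seed) %% 2000000000L) + offs
}
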