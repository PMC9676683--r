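# Self-contained differential-expression stage: median-of-ratios size
# factors, a per-gene method-of-moments negative-binomial dispersion, a Wald
# test on log2 fold change, BH adjustment, and DE selection. Deliberately
# minimal (no cross-gene dispersion shrinkage): each step is specified and
# testable on its own.

counts_matrix <- function(counts) {
  assert_columns(counts, "gene_id", "count table")
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over all-positive genes of
#' `count / geometric mean across samples`, then the factors are rescaled
#' so their geometric mean is 1.
#'
#' @param counts Count tibble (`gene_id` + one column per sample).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- counts_matrix(counts)
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep)) abort("size factors need >= 1 gene with all counts > 0")
  lm <- log(m[keep, , drop = FALSE])
  ratios <- exp(lm - rowMeans(lm))
  f <- apply(ratios, 2, median)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(m))
}

#' Per-condition means of normalized counts
#'
#' @param counts Count tibble.
#' @param sample_info Tibble with `sample`, `condition`.
#' @param sf Optional size factors; computed with [size_factors()] if `NULL`.
#' @return Tibble `gene_id` + one column of mean normalized counts per condition.
#' @export
condition_means <- function(counts, sample_info, sf = NULL) {
  m <- counts_matrix(counts)
  sf <- sf %||% size_factors(counts)
  norm <- sweep(m, 2, sf[colnames(m)], "/")
  out <- tibble(gene_id = rownames(m))
  for (cond in unique(sample_info$condition)) {
    smp <- sample_info$sample[sample_info$condition == cond]
    out[[cond]] <- unname(rowMeans(norm[, smp, drop = FALSE]))
  }
  out
}

#' Negative-binomial Wald test between two conditions
#'
#' Counts are normalized by median-of-ratios size factors computed on the
#' samples of the two conditions. Per gene, the NB dispersion is estimated
#' by method of moments, `alpha_c = (s^2 - mean) / mean^2`, within each
#' condition and averaged, clamped to `[1e-8, Inf)`. The log2 fold change
#' uses shrunken means (`+0.5` pseudo-mean); its standard error comes from
#' the NB delta method, `var(mean_c) = (mu + alpha mu^2) / n_c`. The Wald
#' statistic is referred to a t distribution with `n1 + n2 - 2` degrees of
#' freedom (a small-sample correction; replicate numbers here are in the
#' single digits), and p-values are BH-adjusted across genes. Genes with
#' all-zero counts in both conditions get `log2fc = 0`, `p = 1` and are
#' flagged.
#'
#' @param counts Count tibble (`gene_id` + samples).
#' @param sample_info Tibble `sample`, `condition`.
#' @param condition_pair Length-2 character: test condition, then reference.
#' @return A tibble of class `nbde_tbl`: `gene_id`, `base_mean`, `log2fc`,
#'   `se`, `stat`, `pvalue`, `padj`, `dispersion`, `all_zero`.
#' @export
nb_wald_test <- function(counts, sample_info, condition_pair) {
  stopifnot(length(condition_pair) == 2L)
  assert_columns(sample_info, c("sample", "condition"), "sample_info")
  smp <- sample_info[sample_info$condition %in% condition_pair, ]
  if (!all(condition_pair %in% smp$condition)) {
    abort("both conditions of `condition_pair` must appear in sample_info")
  }
  n_by <- table(smp$condition)[condition_pair]
  if (any(n_by < 2L)) abort("need >= 2 replicates per condition")
  sub <- counts[, c("gene_id", smp$sample)]
  sf <- size_factors(sub)
  m <- counts_matrix(sub)
  norm <- sweep(m, 2, sf[colnames(m)], "/")

  s1 <- smp$sample[smp$condition == condition_pair[1]]
  s2 <- smp$sample[smp$condition == condition_pair[2]]
  n1 <- length(s1); n2 <- length(s2)
  m1 <- unname(rowMeans(norm[, s1, drop = FALSE]))
  m2 <- unname(rowMeans(norm[, s2, drop = FALSE]))
  v1 <- unname(apply(norm[, s1, drop = FALSE], 1, var))
  v2 <- unname(apply(norm[, s2, drop = FALSE], 1, var))
  a1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, NA_real_)
  a2 <- ifelse(m2 > 0, (v2 - m2) / m2^2, NA_real_)
  alpha <- rowMeans(cbind(a1, a2), na.rm = TRUE)
  alpha[is.nan(alpha)] <- 0
  alpha <- pmax(alpha, 1e-8)

  log2fc <- log2((m1 + 0.5) / (m2 + 0.5))
  se <- sqrt((m1 + alpha * m1^2) / (n1 * (m1 + 0.5)^2) +
             (m2 + alpha * m2^2) / (n2 * (m2 + 0.5)^2)) / log(2)
  df <- n1 + n2 - 2L
  stat <- ifelse(se > 0, log2fc / se, 0)
  pvalue <- 2 * pt(-abs(stat), df)

  all_zero <- m1 == 0 & m2 == 0
  log2fc[all_zero] <- 0; stat[all_zero] <- 0; pvalue[all_zero] <- 1
  se[all_zero] <- NA_real_

  out <- tibble(
    gene_id = rownames(m),
    base_mean = unname(rowMeans(norm)),
    log2fc = log2fc, se = se, stat = stat, pvalue = pvalue,
    padj = p.adjust(pvalue, method = "BH"),
    dispersion = alpha, all_zero = all_zero
  )
  class(out) <- c("nbde_tbl", class(out))
  attr(out, "condition_pair") <- condition_pair
  attr(out, "size_factors") <- sf
  attr(out, "df") <- df
  out
}

#' Select differentially expressed genes
#'
#' @param de An `nbde_tbl` (or any tibble with `gene_id`, `log2fc`, `padj`).
#' @param lfc_min Minimum absolute log2 fold change (default 1.5).
#' @param fdr BH-adjusted p-value cutoff (default 0.05).
#' @param strict If `FALSE` (default) thresholds are inclusive
#'   (`padj <= fdr`, `|log2fc| >= lfc_min`); if `TRUE`, strict inequalities.
#' @return Tibble of selected genes with a `direction` column (`up`/`down`).
#' @export
select_de <- function(de, lfc_min = 1.5, fdr = 0.05, strict = FALSE) {
  assert_columns(de, c("gene_id", "log2fc", "padj"), "DE table")
  keep <- if (strict) de$padj < fdr & abs(de$log2fc) > lfc_min
          else de$padj <= fdr & abs(de$log2fc) >= lfc_min
  out <- as_tibble(de)[which(keep), c("gene_id", "log2fc", "padj")]
  out$direction <- if_else(out$log2fc > 0, "up", "down")
  out
}

#' Cluster condition-mean expression profiles with PAM
#'
#' Rows (genes) are standardized (z-score across conditions; constant rows
#' become all-zero) and partitioned with the deterministic PAM k-medoids of
#' [pam_kmedoids()] under Euclidean distance. An optional second-level PAM
#' with its own `k` splits one named primary cluster into lettered
#' subclusters (the C-1 -> C-1A/C-1B pattern).
#'
#' @param mean_matrix Tibble `gene_id` + one numeric column per condition
#'   (see [condition_means()]), usually restricted to DE genes.
#' @param k Number of primary clusters.
#' @param subcluster Optional list `list(cluster = i, k = 2)` to subdivide
#'   primary cluster `i`.
#' @param standardize Z-score rows first (default `TRUE`).
#' @return An `expr_clusters` object: `assignments` tibble (`gene_id`,
#'   `cluster`, `label`), `medoids`, `objective`, `objective_trace`, `k`.
#' @export
cluster_de <- function(mean_matrix, k, subcluster = NULL, standardize = TRUE) {
  assert_columns(mean_matrix, "gene_id", "mean matrix")
  x <- as.matrix(mean_matrix[, setdiff(names(mean_matrix), "gene_id")])
  rownames(x) <- mean_matrix$gene_id
  if (k > nrow(x)) abort(sprintf("k = %d exceeds number of genes (%d)", k, nrow(x)))
  if (standardize) {
    mu <- rowMeans(x); s <- apply(x, 1, sd)
    s[s == 0] <- 1
    x <- (x - mu) / s
  }
  fit <- pam_kmedoids(x, k)
  label <- sprintf("C-%d", fit$cluster)

  if (!is.null(subcluster)) {
    ci <- subcluster$cluster
    members <- which(fit$cluster == ci)
    if (length(members) < subcluster$k) abort("subcluster k exceeds cluster size")
    sub <- pam_kmedoids(x[members, , drop = FALSE], subcluster$k)
    label[members] <- sprintf("C-%d%s", ci, LETTERS[sub$cluster])
  }

  structure(
    list(
      assignments = tibble(gene_id = rownames(x), cluster = fit$cluster, label = label),
      medoids = rownames(x)[fit$medoids],
      objective = fit$objective,
      objective_trace = fit$objective_trace,
      k = k,
      matrix = x
    ),
    class = "expr_clusters"
  )
}

#' @export
print.expr_clusters <- function(x, ...) {
  tab <- table(x$assignments$label)
  cat(sprintf("<expr_clusters> k = %d, objective = %.4f\n", x$k, x$objective))
  cat(paste(sprintf("  %s: %d genes", names(tab), as.integer(tab)), collapse = "\n"), "\n")
  invisible(x)
}
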