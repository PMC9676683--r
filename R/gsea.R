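# Gene-set enrichment: weighted Kolmogorov-Smirnov running-sum enrichment
# score, normalized against a gene-set-permutation null, with the standard
# sign-stratified FDR q.

#' Rank genes between two phenotypes
#'
#' Signal-to-noise metric: `(mean1 - mean2) / (sd1 + sd2)`; a zero pooled SD
#' falls back to the conventional `0.2 * |mean|` floor (flagged). `log2fc`
#' is the plain log-ratio of phenotype means, with a 0.5 pseudo-mean only
#' for zero means. Genes are ordered by descending metric, ties broken by
#' gene id.
#'
#' @param counts Count (or normalized expression) tibble, `gene_id` + samples.
#' @param sample_info Tibble `sample`, `condition`.
#' @param phenotype_pair Length-2 character, test phenotype then reference.
#' @param metric `"s2n"` (needs >= 2 samples per phenotype) or `"log2fc"`.
#' @return Tibble `gene_id`, `metric`, descending, class `ranked_list`.
#' @export
rank_genes <- function(counts, sample_info, phenotype_pair,
                       metric = c("s2n", "log2fc")) {
  metric <- match.arg(metric)
  m <- counts_matrix(counts)
  s1 <- sample_info$sample[sample_info$condition == phenotype_pair[1]]
  s2 <- sample_info$sample[sample_info$condition == phenotype_pair[2]]
  if (!length(s1) || !length(s2)) abort("phenotypes not found in sample_info")
  m1 <- unname(rowMeans(m[, s1, drop = FALSE]))
  m2 <- unname(rowMeans(m[, s2, drop = FALSE]))
  if (metric == "s2n") {
    if (length(s1) < 2L || length(s2) < 2L) {
      abort("signal-to-noise needs >= 2 samples per phenotype; use metric = 'log2fc'")
    }
    sd1 <- unname(apply(m[, s1, drop = FALSE], 1, sd))
    sd2 <- unname(apply(m[, s2, drop = FALSE], 1, sd))
    denom <- sd1 + sd2
    # zero pooled SD: fall back to the conventional 0.2 x |mean| floor
    floored <- denom == 0
    denom[floored] <- 0.2 * abs(m1[floored]) + 0.2 * abs(m2[floored])
    val <- ifelse(denom > 0, (m1 - m2) / denom, 0)
    if (any(floored)) {
      warn(sprintf("zero pooled SD: 0.2 x |mean| floor applied for %d gene(s)",
                   sum(floored)))
    }
  } else {
    # pseudo-mean guards only the zero case so non-degenerate ratios are exact
    val <- log2(ifelse(m1 == 0, 0.5, m1) / ifelse(m2 == 0, 0.5, m2))
  }
  out <- tibble(gene_id = rownames(m), metric = val) |>
    arrange(desc(.data$metric), .data$gene_id)
  class(out) <- c("ranked_list", class(out))
  out
}

#' Weighted KS enrichment score
#'
#' Walking down the ranked list, genes in the set increment the running sum
#' by `|metric|^p / sum_set |metric|^p` and genes outside decrement it by
#' `1 / (N - N_set)`; the ES is the running sum's maximum deviation from 0
#' (signed). With `p = 0` this is the classic KS statistic.
#'
#' @param ranked A [rank_genes()] result (or tibble `gene_id`, `metric`,
#'   already in rank order).
#' @param geneset Character vector of gene ids.
#' @param p Weighting exponent (default 1).
#' @return List: `es`, `running` (tibble `rank`, `gene_id`, `score`),
#'   `hits` (logical per rank).
#' @export
enrichment_score <- function(ranked, geneset, p = 1) {
  assert_columns(ranked, c("gene_id", "metric"), "ranked list")
  if (anyDuplicated(ranked$gene_id)) abort("ranked list has duplicate genes")
  hit <- ranked$gene_id %in% geneset
  if (!any(hit)) abort("gene set is disjoint from the ranked list")
  n <- nrow(ranked)
  n_set <- sum(hit)
  if (n_set == n) {
    # degenerate: every gene is a hit; the running sum climbs to exactly 1
    run <- cumsum(abs(ranked$metric)^p / sum(abs(ranked$metric)^p))
    if (!all(is.finite(run))) run <- seq_len(n) / n
    return(list(es = 1,
                running = tibble(rank = seq_len(n), gene_id = ranked$gene_id,
                                 score = run),
                hits = hit))
  }
  w <- abs(ranked$metric)^p
  denom_hit <- sum(w[hit])
  inc <- ifelse(hit, if (denom_hit > 0) w / denom_hit else 1 / n_set,
                -1 / (n - n_set))
  # all-zero weights in the set (p > 0, metric 0): fall back to equal mass
  if (denom_hit == 0) inc[hit] <- 1 / n_set
  run <- cumsum(inc)
  es <- run[which.max(abs(run))]
  list(es = es,
       running = tibble(rank = seq_len(n), gene_id = ranked$gene_id, score = run),
       hits = hit)
}

# ES only, for permutation loops (no running-sum bookkeeping)
es_stat <- function(w_p, hit, n) {
  n_set <- sum(hit)
  denom <- sum(w_p[hit])
  inc <- numeric(n)
  inc[hit] <- if (denom > 0) w_p[hit] / denom else 1 / n_set
  inc[!hit] <- -1 / (n - n_set)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' NES and FDR q by gene-set permutation
#'
#' For each gene set, null enrichment scores come from random gene sets of
#' matching size drawn from the ranked list. `NES = ES / mean(|null ES| of
#' matching sign)`; the nominal p is the fraction of same-sign null ES at
#' least as extreme. FDR q follows the standard sign-stratified pooling:
#' for a set with NES* >= 0, q is the ratio of (fraction of all pooled
#' positive null NES >= NES*) to (fraction of observed positive NES >=
#' NES*), capped at 1; symmetrically for negative NES.
#'
#' @param ranked A [rank_genes()] result.
#' @param genesets Named list of gene-id vectors.
#' @param n_perm Permutations per set size (default 1000; < 100 warns).
#' @param p Weighting exponent for the ES (default 1).
#' @param seed Integer seed making the permutation draw reproducible.
#' @return Tibble of class `gsea_results`: `set`, `size`, `es`, `nes`,
#'   `pval`, `fdr_q`, `n_perm`.
#' @export
nes_fdr <- function(ranked, genesets, n_perm = 1000L, p = 1, seed = 1L) {
  if (n_perm < 100L) warn("n_perm < 100 gives unstable NES and q estimates")
  if (is.null(names(genesets))) abort("`genesets` must be named")
  set.seed(as.integer(seed))
  n <- nrow(ranked)
  w_p <- abs(ranked$metric)^p
  in_list <- lapply(genesets, function(g) which(ranked$gene_id %in% g))
  sizes <- vapply(in_list, length, 0L)
  if (any(sizes == 0L)) {
    abort(sprintf("gene set(s) disjoint from ranked list: %s",
                  paste(names(genesets)[sizes == 0L], collapse = ", ")))
  }

  es_obs <- vapply(names(genesets), function(nm) {
    hit <- logical(n); hit[in_list[[nm]]] <- TRUE
    es_stat(w_p, hit, n)
  }, 0)

  null_by_size <- lapply(unique(sizes), function(sz) {
    vapply(seq_len(n_perm), function(b) {
      hit <- logical(n); hit[sample.int(n, sz)] <- TRUE
      es_stat(w_p, hit, n)
    }, 0)
  })
  names(null_by_size) <- as.character(unique(sizes))

  norm_one <- function(es, null) {
    same <- if (es >= 0) null[null >= 0] else null[null < 0]
    denom <- mean(abs(same))
    if (!length(same) || denom == 0) return(c(nes = NA_real_, pval = NA_real_))
    nes <- es / denom
    pval <- (sum(abs(same) >= abs(es)) + 1) / (length(same) + 1)
    c(nes = nes, pval = pval)
  }
  np <- t(vapply(names(genesets), function(nm) {
    norm_one(es_obs[[nm]], null_by_size[[as.character(sizes[[nm]])]])
  }, c(nes = 0, pval = 0)))

  # pooled null NES for the FDR: normalize every null ES by its size-matched
  # same-sign mean
  null_nes <- unlist(lapply(names(null_by_size), function(sz) {
    null <- null_by_size[[sz]]
    pos <- mean(null[null >= 0]); neg <- mean(abs(null[null < 0]))
    ifelse(null >= 0, null / pos, null / neg)
  }))
  obs_nes <- np[, "nes"]
  fdr_of <- function(nes) {
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      num <- mean(null_nes[null_nes >= 0] >= nes)
      den <- mean(obs_nes[obs_nes >= 0] >= nes)
    } else {
      num <- mean(null_nes[null_nes < 0] <= nes)
      den <- mean(obs_nes[obs_nes < 0] <= nes)
    }
    if (is.nan(den) || den == 0) return(1)
    min(1, num / den)
  }
  out <- tibble(
    set = names(genesets), size = unname(sizes), es = unname(es_obs),
    nes = unname(obs_nes), pval = unname(np[, "pval"]),
    fdr_q = vapply(unname(obs_nes), fdr_of, 0), n_perm = n_perm
  )
  class(out) <- c("gsea_results", class(out))
  out
}
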