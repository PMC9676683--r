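# Peak-to-gene assignment: nearest TSS, +/-5 kb expression-cluster
# association, and genomic-feature classes evaluated at the summit.

#' Assign each peak to its nearest TSS
#'
#' The assigned gene minimizes `|summit - TSS|` on the peak's chromosome;
#' exact distance ties break toward the lexicographically smaller gene id.
#' The signed distance is measured in the gene's orientation: negative
#' means the summit lies upstream of the TSS.
#'
#' @param peaks Peak tibble.
#' @param annotation A [genome_annotation()].
#' @return Tibble `name`, `chrom`, `summit`, `gene_id`, `distance`,
#'   `orphan`. Peaks on chromosomes with no genes get `gene_id = NA` and
#'   `orphan = TRUE`.
#' @export
nearest_tss <- function(peaks, annotation) {
  peaks <- validate_peaks(peaks)
  genes <- annotation$genes
  out <- peaks[, c("name", "chrom", "summit")]
  out$gene_id <- NA_character_
  out$distance <- NA_integer_
  for (ch in unique(peaks$chrom)) {
    gi <- which(genes$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (!length(gi)) next
    # order by TSS then gene id so ties resolve to the smaller id
    g <- genes[gi, ][order(genes$tss[gi], genes$gene_id[gi]), ]
    idx <- findInterval(peaks$summit[pi], g$tss)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, nrow(g))
    # genes sharing a TSS: retarget to the first (smallest-id) duplicate,
    # which is valid because duplicates are equidistant
    lo <- match(g$tss[lo], g$tss)
    hi <- match(g$tss[hi], g$tss)
    d_lo <- abs(peaks$summit[pi] - g$tss[lo])
    d_hi <- abs(peaks$summit[pi] - g$tss[hi])
    # tie at equal distance between the two flanking TSS: smaller gene id
    pick_hi <- d_hi < d_lo | (d_hi == d_lo & g$gene_id[hi] < g$gene_id[lo])
    chosen <- ifelse(pick_hi, hi, lo)
    gene <- g$gene_id[chosen]
    tssv <- g$tss[chosen]
    out$gene_id[pi] <- gene
    sign_mult <- ifelse(g$strand[chosen] == "+", 1L, -1L)
    out$distance[pi] <- (peaks$summit[pi] - tssv) * sign_mult
  }
  out$orphan <- is.na(out$gene_id)
  out
}

#' Genomic-feature class of each peak summit
#'
#' Classes are assigned at the summit with fixed priority
#' promoter > exon > intron > downstream > intergenic: promoter is TSS plus
#' `promoter_window` (gene-oriented, inclusive); exon/intron require the
#' summit inside a gene body; downstream is within `downstream` bp past the
#' gene end in gene orientation. Overlapping genes are resolved by that
#' priority, so the counts over classes always partition the peaks.
#'
#' @param peaks Peak tibble.
#' @param annotation A [genome_annotation()].
#' @param promoter_window Length-2 vector, bp around the TSS in gene
#'   orientation (default `c(-3000, 3000)`).
#' @param downstream Max bp past the gene end still called "downstream"
#'   (default 3000).
#' @return Tibble `name`, `feature` with `feature` in
#'   promoter/exon/intron/downstream/intergenic.
#' @export
genomic_features <- function(peaks, annotation,
                             promoter_window = c(-3000, 3000), downstream = 3000) {
  peaks <- validate_peaks(peaks)
  genes <- annotation$genes
  exons <- annotation$exons
  feature <- rep("intergenic", nrow(peaks))

  for (i in seq_len(nrow(peaks))) {
    s <- peaks$summit[i]; ch <- peaks$chrom[i]
    g <- genes[genes$chrom == ch, ]
    if (!nrow(g)) next
    rel <- ifelse(g$strand == "+", s - g$tss, g$tss - s)
    if (any(rel >= promoter_window[1] & rel <= promoter_window[2])) {
      feature[i] <- "promoter"; next
    }
    inside <- g$gene_id[s >= g$start & s < g$end]
    if (length(inside)) {
      e <- exons[exons$gene_id %in% inside, ]
      feature[i] <- if (any(s >= e$start & s < e$end)) "exon" else "intron"
      next
    }
    past <- ifelse(g$strand == "+", s - g$end, g$start - 1L - s)
    if (any(past >= 0 & past < downstream)) feature[i] <- "downstream"
  }
  tibble(name = peaks$name, feature = feature)
}

#' Associate peak groups with expression clusters (+/- window around TSS)
#'
#' A peak counts for cluster `c` iff its summit lies within `window` bp
#' (inclusive) of the TSS of at least one gene carrying label `c`. A peak
#' near genes of two clusters counts once per cluster; such multi-counted
#' peaks are flagged. Fractions divide by the group's total peak count, so
#' they sum to <= 1 per group (the remainder being peaks near no clustered
#' gene).
#'
#' @param peaks Peak tibble with a `group` column (e.g. the `membership`
#'   from [classify_pair()]).
#' @param clusters An [cluster_de()] result or a tibble `gene_id`, `label`.
#' @param annotation A [genome_annotation()].
#' @param window Half-width in bp (default 5000, inclusive at the boundary).
#' @return Tibble `group`, `label`, `n`, `fraction`, with
#'   `attr(., "multi_counted")` naming peaks counted for several clusters.
#' @export
cluster_association <- function(peaks, clusters, annotation, window = 5000) {
  peaks <- validate_peaks(assert_columns(peaks, "group", "peak table"))
  lab <- if (inherits(clusters, "expr_clusters")) clusters$assignments else as_tibble(clusters)
  assert_columns(lab, c("gene_id", "label"), "cluster table")
  genes <- inner_join(annotation$genes, lab, by = "gene_id")

  pg <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(peaks$summit + 1L,
                                                             peaks$summit + 1L))
  # inclusive +/- window around the TSS, in closed 1-based coordinates
  tg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(pmax(genes$tss - window, 0) + 1L,
                                                genes$tss + window + 1L))
  hits <- GenomicRanges::findOverlaps(pg, tg)
  assoc <- tibble(
    name = peaks$name[S4Vectors::queryHits(hits)],
    group = peaks$group[S4Vectors::queryHits(hits)],
    label = genes$label[S4Vectors::subjectHits(hits)]
  ) |> distinct()

  multi <- assoc |> count(.data$name) |> filter(.data$n > 1L) |> pull(.data$name)
  totals <- count(peaks, .data$group, name = "group_total")
  out <- assoc |>
    count(.data$group, .data$label) |>
    tidyr::complete(group = unique(peaks$group), label = sort(unique(lab$label)),
                    fill = list(n = 0L)) |>
    left_join(totals, by = "group") |>
    mutate(fraction = if_else(.data$group_total > 0, .data$n / .data$group_total, 0)) |>
    select("group", "label", "n", "fraction")
  attr(out, "multi_counted") <- multi
  out
}
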