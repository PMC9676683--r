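# Known-motif scanning in summit-centred windows. Consensus motifs use the
# IUPAC degenerate alphabet (exact match by default); PWMs are scored as
# log2-odds against a uniform background. Both strands are scanned; hit
# offsets are the genomic start of the match (leftmost base) relative to
# the summit.

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# log2-odds matrix (4 x L, rows ACGT) from a probability PWM (L x 4)
pwm_logodds <- function(pwm) {
  t(log2(pmax(pwm, 1e-9) / 0.25))
}

scan_one_strand <- function(seq, motif, strand) {
  if (motif$kind == "consensus") {
    pat <- if (strand == "+") motif$consensus else revcomp(motif$consensus)
    m <- Biostrings::matchPattern(pat, seq, max.mismatch = motif$max_mismatch,
                                  fixed = FALSE)
    tibble(pos = IRanges::start(m), width = IRanges::width(m),
           score = NA_real_, strand = strand)
  } else {
    lo <- pwm_logodds(motif$pwm[[1]])
    if (strand == "-") lo <- Biostrings::reverseComplement(lo)
    if (length(seq) < ncol(lo)) return(tibble(pos = integer(), width = integer(),
                                              score = numeric(), strand = character()))
    m <- Biostrings::matchPWM(lo, seq, min.score = motif$threshold, with.score = TRUE)
    tibble(pos = IRanges::start(m), width = IRanges::width(m),
           score = S4Vectors::mcols(m)$score, strand = strand)
  }
}

#' Scan summit-centred windows for motif occurrences
#'
#' Each peak contributes the window `[summit - halfwidth, summit + halfwidth)`
#' (clipped and flagged at sequence ends); both strands are scanned. A
#' palindromic motif matches both strands at the same position; with
#' `dedup = TRUE` (default) such double hits collapse to one.
#'
#' @param peaks Peak tibble.
#' @param genome A `DNAStringSet` covering the peaks' chromosomes.
#' @param motifs Motif tibble ([read_motifs()] layout); all rows are scanned.
#' @param halfwidth Scan half-width in bp (default 125, i.e. a 250 bp window).
#' @param dedup Collapse same-position opposite-strand duplicate matches.
#' @return Hit tibble: `name` (peak), `motif`, `strand`, `offset` (hit start
#'   relative to summit, signed), `hit_start` (genomic), `width`, `score`,
#'   `clipped`.
#' @export
scan_window <- function(peaks, genome, motifs, halfwidth = 125L, dedup = TRUE) {
  peaks <- validate_peaks(peaks)
  missing_ch <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_ch)) {
    abort(sprintf("genome lacks chromosome(s): %s", paste(missing_ch, collapse = ", ")))
  }
  res <- list()
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]; s <- peaks$summit[i]
    clen <- length(genome[[ch]])
    ws <- max(s - halfwidth, 0L)
    we <- min(s + halfwidth, clen)
    clipped <- (ws != s - halfwidth) || (we != s + halfwidth)
    win <- Biostrings::subseq(genome[[ch]], ws + 1L, we)
    for (j in seq_len(nrow(motifs))) {
      motif <- motifs[j, ]
      hits <- bind_rows(scan_one_strand(win, motif, "+"),
                        scan_one_strand(win, motif, "-"))
      if (!nrow(hits)) next
      hits$name <- peaks$name[i]
      hits$motif <- motif$name
      hits$hit_start <- ws + hits$pos - 1L
      hits$offset <- hits$hit_start - s
      hits$clipped <- clipped
      res[[length(res) + 1L]] <- hits
    }
  }
  if (!length(res)) {
    return(tibble(name = character(), motif = character(), strand = character(),
                  offset = integer(), hit_start = integer(), width = integer(),
                  score = numeric(), clipped = logical()))
  }
  out <- bind_rows(res)
  if (dedup) {
    out <- out |>
      group_by(.data$name, .data$motif, .data$hit_start, .data$width) |>
      slice_min(.data$strand, n = 1, with_ties = FALSE) |>
      ungroup()
  }
  out <- arrange(out, .data$name, .data$motif, .data$hit_start, .data$strand)
  out[, c("name", "motif", "strand", "offset", "hit_start", "width", "score", "clipped")]
}

#' Motif-instance counts per peak
#'
#' @param hits Hit tibble from [scan_window()].
#' @param peaks Peak tibble (peaks without hits get count 0).
#' @param motif Optional motif name to restrict to (default: all hits).
#' @return Tibble `name`, `count`.
#' @export
counts_per_peak <- function(hits, peaks, motif = NULL) {
  peaks <- validate_peaks(peaks)
  if (!is.null(motif)) hits <- hits[hits$motif %in% motif, ]
  cnt <- count(hits, .data$name)
  out <- left_join(peaks[, "name", drop = FALSE], cnt, by = "name") |>
    mutate(count = if_else(is.na(.data$n), 0L, .data$n)) |>
    select("name", "count")
  out
}

#' Per-group motif-count histogram
#'
#' Summarises [counts_per_peak()] output per peak group into the occurrence
#' classes 0 / 1 / 2 / 3+ and the fraction of peaks with at least one hit.
#'
#' @param peak_counts Output of [counts_per_peak()].
#' @param groups Tibble `name`, `group` (or a peak tibble with a `group`
#'   column).
#' @return Tibble `group`, `bin`, `n`, `fraction`, plus a `frac_ge1` column
#'   repeated within group.
#' @export
motif_histogram <- function(peak_counts, groups) {
  assert_columns(groups, c("name", "group"), "groups")
  df <- inner_join(peak_counts, as_tibble(groups)[, c("name", "group")], by = "name")
  df$bin <- dplyr::case_when(
    df$count >= 3L ~ "3+",
    TRUE ~ as.character(df$count)
  )
  out <- df |>
    count(.data$group, .data$bin) |>
    tidyr::complete(group = unique(df$group), bin = c("0", "1", "2", "3+"),
                    fill = list(n = 0L)) |>
    group_by(.data$group) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
  ge1 <- df |>
    group_by(.data$group) |>
    summarise(frac_ge1 = mean(.data$count >= 1L), .groups = "drop")
  left_join(out, ge1, by = "group")
}

#' Positional distribution of motif hits around summits
#'
#' Offsets are binned over `[-halfwidth, halfwidth)`; the curve value is the
#' fraction of peaks carrying at least one hit starting in the bin.
#'
#' @param hits Hit tibble from [scan_window()].
#' @param n_peaks Total number of scanned peaks (the normalizer).
#' @param binsize Bin width (bp); must divide `2 * halfwidth`.
#' @param halfwidth Scan half-width used in the scan (default 125).
#' @param motif_names Motifs to lay the grid over (defaults to those seen in
#'   `hits`; pass explicitly to get all-zero curves for motifs with no hits).
#' @return Tibble `motif`, `bin_start`, `bin_mid`, `fraction`, with
#'   `2 * halfwidth / binsize` rows per motif.
#' @export
positional_distribution <- function(hits, n_peaks, binsize = 10L, halfwidth = 125L,
                                    motif_names = unique(hits$motif)) {
  if ((2L * halfwidth) %% binsize != 0L) {
    abort("binsize must divide 2 * halfwidth")
  }
  edges <- seq(-halfwidth, halfwidth, by = binsize)
  grid <- tidyr::expand_grid(motif = motif_names,
                             bin_start = as.integer(edges[-length(edges)]))
  binned <- hits |>
    filter(.data$offset >= -halfwidth, .data$offset < halfwidth) |>
    mutate(bin_start = as.integer(floor((.data$offset + halfwidth) / binsize) * binsize
                                  - halfwidth)) |>
    distinct(.data$motif, .data$name, .data$bin_start) |>
    count(.data$motif, .data$bin_start)
  out <- left_join(grid, binned, by = c("motif", "bin_start")) |>
    mutate(n = if_else(is.na(.data$n), 0L, .data$n),
           bin_mid = .data$bin_start + binsize / 2,
           fraction = .data$n / n_peaks) |>
    select("motif", "bin_start", "bin_mid", "fraction")
  out
}

#' Partition peaks by motif content
#'
#' Three classes: `own_only` (>= 1 hit of the TF's own motif and no E-box),
#' `ebox_containing` (>= 1 E-box hit, regardless of own-motif hits), and
#' `neither`. The classes are disjoint and exhaustive over the peaks.
#'
#' @param peaks Peak tibble.
#' @param hits Hit tibble covering scans for both motifs.
#' @param own_motif,ebox_motif Motif names.
#' @return Tibble `name`, `motif_class`.
#' @export
partition_by_motif <- function(peaks, hits, own_motif, ebox_motif) {
  peaks <- validate_peaks(peaks)
  has_own <- unique(hits$name[hits$motif == own_motif])
  has_ebox <- unique(hits$name[hits$motif == ebox_motif])
  tibble(
    name = peaks$name,
    motif_class = dplyr::case_when(
      peaks$name %in% has_ebox ~ "ebox_containing",
      peaks$name %in% has_own ~ "own_only",
      TRUE ~ "neither"
    )
  )
}
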