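# Summit-window algebra. A peak's window is the w bp centred on its summit;
# two peaks "overlap" when their windows share >= 1 bp under half-open
# interval arithmetic. All classifications below are defined purely on
# these windows, never on the original peak intervals.

#' Summit-centred windows
#'
#' For window width `w` the window of a summit `s` is `[s - w/2, s + w/2)`
#' (integer division for odd `w`), clipped to `[0, chromosome length)` when
#' lengths are supplied.
#'
#' @param peaks Peak tibble (see [validate_peaks()]).
#' @param w Window width in bp (default 300).
#' @param chrom_lengths Named vector of chromosome lengths; required when
#'   `clip = TRUE` would need the right bound.
#' @param clip Clip windows at chromosome bounds (default `TRUE`; the left
#'   bound 0 never needs `chrom_lengths`).
#' @return The peak tibble with `window_start`, `window_end` columns added.
#' @export
summit_windows <- function(peaks, w = 300L, chrom_lengths = NULL, clip = TRUE) {
  peaks <- validate_peaks(peaks)
  assert_scalar_number(w, "w", positive = TRUE)
  half <- w %/% 2L
  ws <- peaks$summit - half
  we <- ws + as.integer(w)
  if (clip) {
    ws <- pmax(ws, 0L)
    if (!is.null(chrom_lengths)) {
      missing_ch <- setdiff(unique(peaks$chrom), names(chrom_lengths))
      if (length(missing_ch)) {
        abort(sprintf("no chromosome length for: %s", paste(missing_ch, collapse = ", ")))
      }
      we <- pmin(we, as.integer(chrom_lengths[peaks$chrom]))
    }
  }
  peaks$window_start <- as.integer(ws)
  peaks$window_end <- as.integer(we)
  peaks
}

windows_granges <- function(wpeaks) {
  GenomicRanges::GRanges(
    seqnames = wpeaks$chrom,
    ranges = as_iranges0(wpeaks$window_start, wpeaks$window_end)
  )
}

#' Classify two peak sets into unique/common groups
#'
#' A peak is "common" iff its summit window overlaps (>= 1 bp) at least one
#' summit window of the other set; otherwise it is unique to its own set.
#' The classification is symmetric: swapping the inputs exchanges the
#' `A_unique`/`B_unique` labels and leaves `common` fixed.
#'
#' @param peaks_a,peaks_b Peak tibbles.
#' @param w Summit-window width (default 300).
#' @param set_names Length-2 labels used in output (default `c("A", "B")`).
#' @param chrom_lengths Optional, passed to [summit_windows()].
#' @return Tibble of all peaks from both sets with columns `set` and
#'   `membership` (`<A>_unique`, `common`, `<B>_unique`); the per-class
#'   counts are `attr(., "counts")`.
#' @export
classify_pair <- function(peaks_a, peaks_b, w = 300L, set_names = c("A", "B"),
                          chrom_lengths = NULL) {
  wa <- summit_windows(peaks_a, w, chrom_lengths)
  wb <- summit_windows(peaks_b, w, chrom_lengths)
  ga <- windows_granges(wa); gb <- windows_granges(wb)
  hits <- GenomicRanges::findOverlaps(ga, gb, minoverlap = 1L)
  common_a <- unique(S4Vectors::queryHits(hits))
  common_b <- unique(S4Vectors::subjectHits(hits))
  wa$set <- set_names[1]
  wb$set <- set_names[2]
  wa$membership <- if_else(seq_len(nrow(wa)) %in% common_a,
                           "common", paste0(set_names[1], "_unique"))
  wb$membership <- if_else(seq_len(nrow(wb)) %in% common_b,
                           "common", paste0(set_names[2], "_unique"))
  out <- bind_rows(wa, wb)
  lev <- c(paste0(set_names[1], "_unique"), "common", paste0(set_names[2], "_unique"))
  attr(out, "counts") <- tibble(
    membership = lev,
    n = unname(vapply(lev, function(l) sum(out$membership == l), 0L))
  )
  out
}

#' Generalized Venn partition of k peak sets
#'
#' Summit windows from all sets are pooled and merged transitively
#' (single linkage on >= 1 bp overlap), so a chain of pairwise-overlapping
#' windows collapses into one region even when its ends do not overlap each
#' other. Each merged region is labelled with the set of contributing
#' set names; the 2^k - 1 possible labels are the generalized Venn classes.
#' Counts are reported both as merged regions and as contributing source
#' peaks, which differ whenever several peaks of one set merge.
#'
#' @param peak_sets Named list (length >= 2) of peak tibbles.
#' @param w Summit-window width (default 300).
#' @param chrom_lengths Optional, passed to [summit_windows()].
#' @return A `membership_partition` object: `regions` (tibble `region_id`,
#'   `chrom`, `start`, `end`, `members`, `n_members`), `contributions`
#'   (tibble `region_id`, `set`, `name`), and `w`.
#' @export
membership_partition <- function(peak_sets, w = 300L, chrom_lengths = NULL) {
  if (is.null(names(peak_sets)) || any(!nzchar(names(peak_sets)))) {
    abort("`peak_sets` must be a named list")
  }
  if (length(peak_sets) < 2L) abort("need >= 2 peak sets")
  pooled <- bind_rows(lapply(names(peak_sets), function(nm) {
    wp <- summit_windows(peak_sets[[nm]], w, chrom_lengths)
    wp$set <- nm
    wp[, c("chrom", "window_start", "window_end", "name", "set")]
  }))
  gr <- GenomicRanges::GRanges(pooled$chrom,
                               as_iranges0(pooled$window_start, pooled$window_end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  ov <- GenomicRanges::findOverlaps(gr, merged, minoverlap = 1L)
  stopifnot(length(ov) == nrow(pooled))  # every window lands in exactly one region
  pooled$region_id <- S4Vectors::subjectHits(ov)

  members <- pooled |>
    group_by(.data$region_id) |>
    summarise(members = paste(sort(unique(.data$set)), collapse = "+"),
              n_members = dplyr::n_distinct(.data$set), .groups = "drop")
  coords <- tibble(
    region_id = seq_along(merged),
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = IRanges::start(merged) - 1L,
    end = IRanges::end(merged)
  )
  regions <- inner_join(coords, members, by = "region_id")
  structure(
    list(regions = regions,
         contributions = pooled[, c("region_id", "set", "name")],
         w = w, set_names = names(peak_sets)),
    class = "membership_partition"
  )
}

#' Per-class counts of a membership partition
#'
#' @param partition A [membership_partition()].
#' @return Tibble with one row per observed membership class: `members`,
#'   `n_regions` (merged regions) and `n_peaks` (contributing source peaks).
#' @export
partition_counts <- function(partition) {
  stopifnot(inherits(partition, "membership_partition"))
  regions <- partition$regions
  contrib <- count(inner_join(partition$contributions,
                              regions[, c("region_id", "members")], by = "region_id"),
                   .data$members, name = "n_peaks")
  reg <- count(regions, .data$members, name = "n_regions")
  inner_join(reg, contrib, by = "members") |> arrange(desc(.data$n_regions))
}

#' @export
print.membership_partition <- function(x, ...) {
  cat(sprintf("<membership_partition> %d sets, %d merged regions (w = %d)\n",
              length(x$set_names), nrow(x$regions), x$w))
  print(partition_counts(x))
  invisible(x)
}

#' @export
tidy.membership_partition <- function(x, ...) {
  inner_join(x$contributions, x$regions, by = "region_id")
}

#' @export
glance.membership_partition <- function(x, ...) {
  tibble(n_sets = length(x$set_names), n_regions = nrow(x$regions),
         n_peaks = nrow(x$contributions),
         n_classes = dplyr::n_distinct(x$regions$members), w = x$w)
}

#' Export per-class BED files of a partition
#'
#' @param partition A [membership_partition()].
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_partition_beds <- function(partition, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (cls in unique(partition$regions$members)) {
    sub <- partition$regions[partition$regions$members == cls, ]
    path <- file.path(dir, paste0(gsub("\\+", "_", cls), ".bed"))
    readr::write_tsv(
      tibble(sub$chrom, sub$start, sub$end, sprintf("region_%d", sub$region_id)),
      path, col_names = FALSE, progress = FALSE
    )
    paths <- c(paths, path)
  }
  invisible(paths)
}
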