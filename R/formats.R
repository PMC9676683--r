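# Readers/writers for the plain-text formats the pipeline touches. All
# readers validate and report 1-based file line numbers on failure; all
# writers emit files their readers accept.

NARROWPEAK_COLS <- c("chrom", "start", "end", "name", "score", "strand",
                     "signal", "pval", "qval", "peak")

#' Read an ENCODE narrowPeak file
#'
#' narrowPeak is BED6+4: the tenth column is the summit offset from `start`,
#' or -1 when no summit was called. Coordinates are kept 0-based half-open.
#'
#' @param path Path to a 10-column narrowPeak file.
#' @return A peak tibble (see [validate_peaks()]) with an absolute `summit`
#'   column; an offset of -1 falls back to the interval midpoint
#'   (`floor((start + end) / 2)`). Row order follows the file.
#' @export
read_narrowpeak <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 10L) {
    abort(sprintf("%s: narrowPeak needs 10 columns, found %d", path, ncol(raw)))
  }
  raw <- raw[, 1:10]
  names(raw) <- NARROWPEAK_COLS
  num <- c("start", "end", "score", "signal", "pval", "qval", "peak")
  for (col in num) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort(sprintf("%s line %d: column '%s' is not numeric (%s)",
                    path, bad[1], col, raw[[col]][bad[1]]))
    }
    raw[[col]] <- v
  }
  raw$start <- as.integer(raw$start)
  raw$end <- as.integer(raw$end)
  raw$peak <- as.integer(raw$peak)
  if (!all(raw$strand %in% c("+", "-", "."))) {
    bad <- which(!raw$strand %in% c("+", "-", "."))[1]
    abort(sprintf("%s line %d: invalid strand '%s'", path, bad, raw$strand[bad]))
  }
  peaks <- raw
  peaks$summit <- ifelse(peaks$peak < 0L,
                         (peaks$start + peaks$end) %/% 2L,
                         peaks$start + peaks$peak)
  peaks$summit <- as.integer(peaks$summit)
  bad <- which(!(peaks$summit >= peaks$start & peaks$summit < peaks$end))
  if (length(bad)) {
    abort(sprintf("%s line %d: summit offset places summit outside [start, end)",
                  path, bad[1]))
  }
  validate_peaks(peaks[, c(NARROWPEAK_COLS, "summit")])
}

#' Write peaks as ENCODE narrowPeak
#'
#' @param peaks A peak tibble. Missing narrowPeak columns are filled with
#'   defaults (score 0, strand ".", signal/pval/qval 0).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  peaks <- validate_peaks(peaks)
  defaults <- list(score = 0, strand = ".", signal = 0, pval = 0, qval = 0)
  for (col in names(defaults)) {
    if (!col %in% names(peaks)) peaks[[col]] <- defaults[[col]]
  }
  out <- tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = peaks$name, score = peaks$score, strand = peaks$strand,
    signal = peaks$signal, pval = peaks$pval, qval = peaks$qval,
    peak = as.integer(peaks$summit - peaks$start)
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from GTF or BED6
#'
#' GTF (1-based closed) is converted to the package's 0-based half-open
#' convention at this boundary; the strand-aware TSS is `start` for `+`
#' genes and `end - 1` for `-` genes. `gene` features define genes and
#' `exon` features their exon structure (genes lacking exon rows get a
#' single gene-spanning exon). BED6 files are taken as one gene per line.
#'
#' @param path Path to a `.gtf`/`.gff` file or a 6-column BED file.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return A [genome_annotation()].
#' @export
read_gene_models <- function(path, chrom_lengths = NULL) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name", "score", "strand"),
                           col_types = "ciicdc", progress = FALSE)
    if (!all(bed$strand %in% c("+", "-"))) {
      bad <- which(!bed$strand %in% c("+", "-"))[1]
      abort(sprintf("%s line %d: invalid strand '%s'", path, bad, bed$strand[bad]))
    }
    genes <- tibble(gene_id = bed$name, chrom = bed$chrom, start = bed$start,
                    end = bed$end, strand = bed$strand)
    return(genome_annotation(genes, chrom_lengths = chrom_lengths))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  if (!"type" %in% names(df) || !"gene_id" %in% names(df)) {
    abort(sprintf("%s: GTF must carry feature type and gene_id attributes", path))
  }
  if (any(as.character(df$strand) == "*")) {
    abort(sprintf("%s: gene model with unknown strand", path))
  }
  gdf <- df[df$type == "gene", ]
  if (!nrow(gdf)) abort(sprintf("%s: no 'gene' features found", path))
  genes <- tibble(
    gene_id = gdf$gene_id,
    chrom = as.character(gdf$seqnames),
    start = as.integer(gdf$start - 1L),
    end = as.integer(gdf$end),
    strand = as.character(gdf$strand)
  )
  edf <- df[df$type == "exon", ]
  exons <- if (nrow(edf)) {
    tibble(gene_id = edf$gene_id, chrom = as.character(edf$seqnames),
           start = as.integer(edf$start - 1L), end = as.integer(edf$end))
  } else NULL
  if (!is.null(exons)) {
    orphan <- dplyr::anti_join(genes[, "gene_id"], exons[, "gene_id"], by = "gene_id")
    if (nrow(orphan)) {
      exons <- bind_rows(exons,
                         genes[genes$gene_id %in% orphan$gene_id,
                               c("gene_id", "chrom", "start", "end")])
    }
  }
  genome_annotation(genes, exons = exons, chrom_lengths = chrom_lengths)
}

#' Write gene models as GTF
#'
#' Emits `gene` and `exon` features with 1-based closed coordinates and a
#' `gene_id` attribute, the subset of GTF that [read_gene_models()] consumes.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  fmt <- function(df, type, strand) {
    sprintf("%s\tpeakcross\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            df$chrom, type, df$start + 1L, df$end, strand, df$gene_id)
  }
  g <- annotation$genes
  e <- left_join(annotation$exons, g[, c("gene_id", "strand")], by = "gene_id")
  lines <- c(fmt(g, "gene", g$strand), fmt(e, "exon", e$strand))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a gene-level count matrix
#'
#' The TSV has a header row, genes in the first column (`gene_id`) and one
#' integer column per sample. Counts must be non-negative integers.
#'
#' @param path Path to the TSV.
#' @return A tibble with `gene_id` plus one column per sample.
#' @export
read_counts <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  if (ncol(tab) < 2L) abort(sprintf("%s: count matrix needs gene ids plus >= 1 sample", path))
  names(tab)[1] <- "gene_id"
  if (anyDuplicated(tab$gene_id)) abort(sprintf("%s: duplicate gene ids", path))
  for (col in names(tab)[-1]) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      abort(sprintf("%s line %d: count '%s' in sample '%s' is not a non-negative integer",
                    path, bad[1] + 1L, tab[[col]][bad[1]], col))
    }
    tab[[col]] <- as.integer(v)
  }
  tab
}

#' @rdname read_counts
#' @param counts Tibble as returned by [read_counts()].
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                 S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                 D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Read / write motif models
#'
#' The motif text format holds one model per record. Consensus records are a
#' single line `NAME CONSENSUS [max_mismatch]`, with the consensus in the
#' IUPAC degenerate alphabet. PWM records start with a header line
#' `>NAME threshold=X` followed by one line per motif position with four
#' probabilities (A C G T order) summing to 1; the threshold is a log2-odds
#' score against a uniform background.
#'
#' @param path Path to the motif file.
#' @return A tibble with columns `name`, `kind` ("consensus" or "pwm"),
#'   `consensus`, `max_mismatch`, `pwm` (list of matrices), `threshold`.
#' @export
read_motifs <- function(path) {
  lines <- readLines(path)
  recs <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) { i <- i + 1L; next }
    if (startsWith(line, ">")) {
      hdr <- strsplit(sub("^>", "", line), "\\s+")[[1]]
      name <- hdr[1]
      thr <- NA_real_
      tpart <- grep("^threshold=", hdr[-1], value = TRUE)
      if (length(tpart)) thr <- as.numeric(sub("threshold=", "", tpart[1]))
      rows <- list()
      j <- i + 1L
      while (j <= length(lines) && !startsWith(trimws(lines[j]), ">") &&
             trimws(lines[j]) != "" && !grepl("^[A-Za-z]", trimws(lines[j]))) {
        vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]]))
        if (length(vals) != 4L || anyNA(vals)) {
          abort(sprintf("%s line %d: PWM row must be 4 numbers", path, j))
        }
        if (abs(sum(vals) - 1) > 1e-6) {
          abort(sprintf("%s line %d: PWM row sums to %.8f, not 1", path, j, sum(vals)))
        }
        rows[[length(rows) + 1L]] <- vals
        j <- j + 1L
      }
      if (length(rows) < 4L) {
        abort(sprintf("%s line %d: PWM '%s' has %d positions; need >= 4",
                      path, i, name, length(rows)))
      }
      pwm <- t(vapply(rows, identity, numeric(4)))
      colnames(pwm) <- c("A", "C", "G", "T")
      if (is.na(thr)) thr <- default_pwm_threshold(pwm)
      recs[[length(recs) + 1L]] <- tibble(
        name = name, kind = "pwm", consensus = NA_character_,
        max_mismatch = NA_integer_, pwm = list(pwm), threshold = thr
      )
      i <- j
    } else {
      parts <- strsplit(line, "\\s+")[[1]]
      if (length(parts) < 2L) {
        abort(sprintf("%s line %d: expected 'NAME CONSENSUS'", path, i))
      }
      cons <- toupper(parts[2])
      badc <- setdiff(strsplit(cons, "")[[1]], names(IUPAC_CODES))
      if (length(badc)) {
        abort(sprintf("%s line %d: invalid IUPAC letter(s) %s", path, i,
                      paste(badc, collapse = ",")))
      }
      if (nchar(cons) < 4L) {
        abort(sprintf("%s line %d: motif length %d < 4", path, i, nchar(cons)))
      }
      mm <- if (length(parts) >= 3L) as.integer(parts[3]) else 0L
      recs[[length(recs) + 1L]] <- tibble(
        name = parts[1], kind = "consensus", consensus = cons,
        max_mismatch = mm, pwm = list(NULL), threshold = NA_real_
      )
      i <- i + 1L
    }
  }
  if (!length(recs)) abort(sprintf("%s: no motif records found", path))
  out <- bind_rows(recs)
  if (anyDuplicated(out$name)) abort(sprintf("%s: duplicate motif name", path))
  out
}

# 80% of the maximal attainable log2-odds score: a conventional stringent
# default when no threshold is given.
default_pwm_threshold <- function(pwm) {
  0.8 * sum(log2(apply(pwm, 1, max) / 0.25))
}

#' @rdname read_motifs
#' @param motifs Motif tibble as returned by [read_motifs()].
#' @export
write_motifs <- function(motifs, path) {
  lines <- character(0)
  for (i in seq_len(nrow(motifs))) {
    if (motifs$kind[i] == "consensus") {
      lines <- c(lines, sprintf("%s\t%s\t%d", motifs$name[i], motifs$consensus[i],
                                motifs$max_mismatch[i]))
    } else {
      pwm <- motifs$pwm[[i]]
      lines <- c(lines,
                 sprintf(">%s threshold=%.6g", motifs$name[i], motifs$threshold[i]),
                 apply(pwm, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write genome FASTA
#'
#' Thin wrappers over Biostrings with 60-column wrapping on write.
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param genome A `DNAStringSet`.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' @param path GMT path (set name, description, then member genes, tab-separated).
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) abort(sprintf("%s line %d: GMT rows need name, description, >=1 gene",
                                 path, bad[1]))
  setNames(lapply(parts, function(p) p[-(1:2)]), vapply(parts, `[`, "", 1))
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
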