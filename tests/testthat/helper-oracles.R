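# Fixture builders and independent brute-force oracles. The oracles share
# no code with the implementation: pair/partition classification is checked
# by all-pairs interval intersection, nearest-TSS by a linear scan, motif
# scanning by per-position comparison, and the enrichment score by a direct
# KS running sum.

mini_peak <- function(summit, chrom = "chr1", name = paste0("p", summit)) {
  tibble::tibble(chrom = chrom, start = pmax(summit - 200L, 0L), end = summit + 200L,
                 name = name, score = 0, strand = ".", signal = 0, pval = 0,
                 qval = 0, summit = summit)
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), chrom_len = 100000L,
                         prefix = "p", halfwidth = 200L) {
  summit <- sample.int(chrom_len - 2L * halfwidth, n, replace = TRUE) + halfwidth
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = summit - halfwidth, end = summit + halfwidth,
    name = sprintf("%s%04d", prefix, seq_len(n)),
    score = 0, strand = ".", signal = 0, pval = 0, qval = 0,
    summit = summit
  )
}

random_annotation <- function(n_genes, chroms = c("chr1", "chr2"),
                              chrom_len = 100000L) {
  start <- sample.int(chrom_len - 3000L, n_genes, replace = TRUE)
  len <- sample(500:2000, n_genes, replace = TRUE)
  peakcross::genome_annotation(tibble::tibble(
    gene_id = sprintf("g%04d", sample.int(9999L, n_genes)),
    chrom = sample(chroms, n_genes, replace = TRUE),
    start = start, end = start + len,
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  ))
}

# windows under half-open arithmetic, as plain vectors
oracle_windows <- function(peaks, w) {
  half <- w %/% 2L
  list(start = pmax(peaks$summit - half, 0L), end = peaks$summit - half + w,
       chrom = peaks$chrom)
}

# TRUE at [i] iff window i of a overlaps >= 1 bp with any window of b
oracle_overlaps_any <- function(a, b, w) {
  wa <- oracle_windows(a, w); wb <- oracle_windows(b, w)
  vapply(seq_len(nrow(a)), function(i) {
    same <- wb$chrom == wa$chrom[i]
    any(pmin(wa$end[i], wb$end[same]) - pmax(wa$start[i], wb$start[same]) >= 1L)
  }, TRUE)
}

# transitive merge by repeated sweeps; returns component id per pooled window
oracle_components <- function(pooled, w) {
  wp <- oracle_windows(pooled, w)
  n <- nrow(pooled)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      touch <- which(wp$chrom == wp$chrom[i] &
                     pmin(wp$end[i], wp$end) - pmax(wp$start[i], wp$start) >= 1L)
      new <- min(comp[touch])
      if (any(comp[touch] != new)) { comp[touch] <- new; changed <- TRUE }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

oracle_nearest_tss <- function(peaks, annotation) {
  genes <- annotation$genes
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], ]
    if (!nrow(g)) return(tibble::tibble(gene_id = NA_character_, distance = NA_integer_))
    d <- abs(peaks$summit[i] - g$tss)
    cand <- g[d == min(d), ]
    cand <- cand[order(cand$gene_id), ][1, ]
    sgn <- if (cand$strand == "+") 1L else -1L
    tibble::tibble(gene_id = cand$gene_id,
                   distance = (peaks$summit[i] - cand$tss) * sgn)
  })
  dplyr::bind_rows(out)
}

IUPAC_MAP <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
               S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
               D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# positions (1-based) where the degenerate consensus matches seq exactly
oracle_consensus_positions <- function(seq, consensus) {
  L <- nchar(consensus); n <- nchar(seq)
  if (n < L) return(integer(0))
  sc <- strsplit(seq, "")[[1]]
  cc <- strsplit(consensus, "")[[1]]
  ok <- vapply(seq_len(n - L + 1L), function(p) {
    all(vapply(seq_len(L), function(j) {
      grepl(sc[p + j - 1L], IUPAC_MAP[[cc[j]]], fixed = TRUE)
    }, TRUE))
  }, TRUE)
  which(ok)
}

# positions where the log2-odds PWM score >= threshold
oracle_pwm_positions <- function(seq, pwm, threshold) {
  L <- nrow(pwm); n <- nchar(seq)
  if (n < L) return(integer(0))
  sc <- strsplit(seq, "")[[1]]
  lo <- log2(pmax(pwm, 1e-9) / 0.25)
  score <- vapply(seq_len(n - L + 1L), function(p) {
    sum(vapply(seq_len(L), function(j) lo[j, sc[p + j - 1L]], 0))
  }, 0)
  which(score >= threshold)
}

# classic KS running-sum enrichment score (p = 0), written independently
oracle_ks_es <- function(n, hit_ranks) {
  hit <- seq_len(n) %in% hit_ranks
  nh <- length(hit_ranks)
  run <- cumsum(ifelse(hit, 1 / nh, -1 / (n - nh)))
  run[which.max(abs(run))]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

ranked_fixture <- function(n, seed = 1) {
  set.seed(seed)
  out <- tibble::tibble(gene_id = sprintf("g%04d", 1:n),
                        metric = sort(rnorm(n, 0, 1.5), decreasing = TRUE))
  class(out) <- c("ranked_list", class(out))
  out
}

# small scenario + report, computed once and reused across test files
shared_cache <- new.env(parent = emptyenv())

shared_scenario <- function() {
  if (is.null(shared_cache$sc)) {
    shared_cache$sc <- peakcross::simulate_gpa_scenario(peakcross::gpa_scenario_spec(seed = 11L))
  }
  shared_cache$sc
}

shared_report <- function() {
  if (is.null(shared_cache$rep)) {
    shared_cache$rep <- suppressWarnings(peakcross::run_gpa_pipeline(
      shared_scenario(), peakcross::pipeline_params(n_perm = 200L, seed = 5L)
    ))
  }
  shared_cache$rep
}
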