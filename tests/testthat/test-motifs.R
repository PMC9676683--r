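genome_with <- function(window, pad = 200L) {
  # chromosome = pad Ns-equivalent random bases, the window, more pad
  set.seed(1)
  seq <- paste0(random_dna(pad), window, random_dna(pad))
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- "chr1"
  g
}

consensus_motif <- function(name, consensus, mm = 0L) {
  tibble::tibble(name = name, kind = "consensus", consensus = consensus,
                 max_mismatch = mm, pwm = list(NULL), threshold = NA_real_)
}

test_that("a hit's offset is its start relative to the summit", {
  # window TTCAGCTGAA centred on the summit: CAGCTG starts 3 bp left of centre
  g <- genome_with("TTCAGCTGAA")
  summit <- 200L + 5L
  pk <- mini_peak(summit)
  hits <- scan_window(pk, g, consensus_motif("ebox", "CAGCTG"), halfwidth = 5L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, -3L)

  none <- scan_window(pk, g, consensus_motif("zzz", "AAAAAAAAAA"), halfwidth = 5L)
  expect_equal(nrow(none), 0L)
})

test_that("consensus scanning agrees with the per-position IUPAC oracle", {
  for (seed in 1:8) {
    set.seed(seed + 300)
    win <- random_dna(250)
    g <- genome_with(win, pad = 100L)
    pk <- mini_peak(100L + 125L)
    cons <- sample(c("CAGSTG", "TAAWT", "RCGCGY"), 1)
    hits <- scan_window(pk, g, consensus_motif("m", cons), halfwidth = 125L,
                        dedup = FALSE)
    fwd <- oracle_consensus_positions(win, cons)
    rev <- oracle_consensus_positions(win, revcomp_chr(cons))
    got_f <- sort(hits$hit_start[hits$strand == "+"] - 100L + 1L)
    got_r <- sort(hits$hit_start[hits$strand == "-"] - 100L + 1L)
    expect_equal(got_f, fwd)
    expect_equal(got_r, rev)
  }
})

test_that("PWM scanning agrees with naive per-position log-odds scoring", {
  set.seed(44)
  pwm <- matrix(0.25, nrow = 6, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm[1, ] <- c(0.7, 0.1, 0.1, 0.1); pwm[2, ] <- c(0.1, 0.7, 0.1, 0.1)
  pwm[3, ] <- c(0.1, 0.1, 0.7, 0.1); pwm[4, ] <- c(0.05, 0.45, 0.45, 0.05)
  pwm[5, ] <- c(0.1, 0.1, 0.1, 0.7); pwm[6, ] <- c(0.1, 0.1, 0.7, 0.1)
  motif <- tibble::tibble(name = "pwm6", kind = "pwm", consensus = NA_character_,
                          max_mismatch = NA_integer_, pwm = list(pwm), threshold = 3)
  for (seed in 1:8) {
    set.seed(seed + 400)
    win <- random_dna(1000)
    g <- genome_with(win, pad = 50L)
    pk <- mini_peak(50L + 500L)
    hits <- scan_window(pk, g, motif, halfwidth = 500L, dedup = FALSE)
    fwd <- oracle_pwm_positions(win, pwm, 3)
    # minus strand: score the reverse complement of the window, map back
    rc <- revcomp_chr(win)
    rev_rc <- oracle_pwm_positions(rc, pwm, 3)
    rev <- sort(nchar(win) - (rev_rc + nrow(pwm) - 1L) + 1L)
    expect_equal(sort(hits$hit_start[hits$strand == "+"] - 50L + 1L), fwd)
    expect_equal(sort(hits$hit_start[hits$strand == "-"] - 50L + 1L), rev)
  }
})

test_that("scanning is strand-consistent under reverse complementation", {
  set.seed(45)
  win <- random_dna(250)
  g1 <- genome_with(win, pad = 60L)
  g2 <- genome_with(revcomp_chr(win), pad = 60L)
  pk <- mini_peak(60L + 125L)
  cons <- "CAGSTG"
  h1 <- scan_window(pk, g1, consensus_motif("m", cons), halfwidth = 125L, dedup = FALSE)
  h2 <- scan_window(pk, g2, consensus_motif("m", revcomp_chr(cons)),
                    halfwidth = 125L, dedup = FALSE)
  # same number of hits, offsets mirrored around the summit
  expect_equal(nrow(h1), nrow(h2))
  mirror <- sort(-h1$offset - nchar(cons))
  expect_equal(sort(h2$offset), mirror)
})

test_that("palindromic motifs deduplicate to one hit per site by default", {
  g <- genome_with("AACACGTGAA")
  pk <- mini_peak(200L + 5L)
  pal <- consensus_motif("pal", "CACGTG")   # own reverse complement
  both <- scan_window(pk, g, pal, halfwidth = 5L, dedup = FALSE)
  expect_equal(nrow(both), 2L)
  expect_setequal(both$strand, c("+", "-"))
  one <- scan_window(pk, g, pal, halfwidth = 5L, dedup = TRUE)
  expect_equal(nrow(one), 1L)
})

test_that("instances outside the scan half-width are excluded", {
  set.seed(46)
  chrom <- paste0(random_dna(400), "CAGCTG", random_dna(400))
  g <- Biostrings::DNAStringSet(chrom); names(g) <- "chr1"
  inst_start <- 400L  # 0-based
  pk_near <- mini_peak(inst_start - 100L, name = "near")   # offset +100
  pk_far <- mini_peak(inst_start - 130L, name = "far")     # offset +130
  hits <- scan_window(dplyr::bind_rows(pk_near, pk_far), g,
                      consensus_motif("ebox", "CAGCTG"), halfwidth = 125L)
  expect_true("near" %in% hits$name)
  expect_false("far" %in% hits$name)
})

test_that("per-peak counts add up to total deduplicated hits", {
  sc <- shared_scenario()
  pk <- sc$peaks[sc$peaks$tf == "A" & sc$peaks$condition == "GPA", ]
  hits <- scan_window(pk, sc$genome, gpa_default_motifs()[1, ])
  counts <- counts_per_peak(hits, pk, motif = "ebox")
  expect_equal(sum(counts$count), nrow(hits))
  expect_true(all(counts$count >= 0))

  grp <- tibble::tibble(name = pk$name, group = "A_GPA")
  hist <- motif_histogram(counts, grp)
  expect_equal(sum(hist$n), nrow(pk))
  expect_equal(unique(hist$frac_ge1), mean(counts$count >= 1))
})

test_that("positional distribution bins offsets and flags bad bin sizes", {
  hits0 <- tibble::tibble(name = sprintf("p%d", 1:10), motif = "m", strand = "+",
                          offset = 0L, hit_start = 0L, width = 6L, score = NA_real_,
                          clipped = FALSE)
  curve <- positional_distribution(hits0, n_peaks = 10)
  expect_equal(nrow(curve), 25L)
  expect_equal(sum(curve$fraction > 0), 1L)
  expect_equal(curve$fraction[curve$bin_mid == 0], 1)  # centre bin is [-5, 5)

  empty <- positional_distribution(hits0[0, ], n_peaks = 10, motif_names = "m")
  expect_equal(nrow(empty), 25L)
  expect_true(all(empty$fraction == 0))

  expect_error(positional_distribution(hits0, n_peaks = 10, binsize = 7),
               "divide")
})

test_that("uniformly placed hits give a flat positional curve", {
  set.seed(47)
  n <- 10000
  hits <- tibble::tibble(name = sprintf("p%06d", seq_len(n)), motif = "m",
                         strand = "+",
                         offset = sample(-125:124, n, replace = TRUE),
                         hit_start = 0L, width = 6L, score = NA_real_,
                         clipped = FALSE)
  curve <- positional_distribution(hits, n_peaks = n)
  p0 <- 10 / 250
  sd_bin <- sqrt(p0 * (1 - p0) / n)
  expect_true(all(abs(curve$fraction - p0) < 3.5 * sd_bin))
})

test_that("motif-content partition is disjoint, exhaustive, and ebox-dominant", {
  pk <- dplyr::bind_rows(mini_peak(1000L, name = "own"),
                         mini_peak(2000L, name = "both"),
                         mini_peak(3000L, name = "none"))
  hits <- tibble::tibble(
    name = c("own", "both", "both"),
    motif = c("gfi1", "gfi1", "ebox"),
    strand = "+", offset = 0L, hit_start = 0L, width = 6L,
    score = NA_real_, clipped = FALSE
  )
  cls <- partition_by_motif(pk, hits, own_motif = "gfi1", ebox_motif = "ebox")
  got <- setNames(cls$motif_class, cls$name)
  expect_equal(unname(got[c("own", "both", "none")]),
               c("own_only", "ebox_containing", "neither"))
  expect_equal(anyDuplicated(cls$name), 0L)
  expect_equal(nrow(cls), nrow(pk))
})
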