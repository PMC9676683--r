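test_that("generators are deterministic under a fixed seed", {
  s1 <- simulate_gpa_scenario(gpa_scenario_spec(seed = 3))
  s2 <- simulate_gpa_scenario(gpa_scenario_spec(seed = 3))
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(as.data.frame(s1$peaks), as.data.frame(s2$peaks))
  expect_identical(as.data.frame(s1$counts), as.data.frame(s2$counts))
  s3 <- simulate_gpa_scenario(gpa_scenario_spec(seed = 4))
  expect_false(identical(as.data.frame(s1$counts), as.data.frame(s3$counts)))
})

test_that("gene models are disjoint with the strand-aware TSS convention", {
  sc <- shared_scenario()
  genes <- sc$annotation$genes
  by_chrom <- split(genes, genes$chrom)
  for (g in by_chrom) {
    g <- g[order(g$start), ]
    expect_true(all(g$end[-nrow(g)] <= g$start[-1]))
  }
  minus <- genes[genes$strand == "-", ]
  plus <- genes[genes$strand == "+", ]
  expect_equal(minus$tss, minus$end - 1L)
  expect_equal(plus$tss, plus$start)
})

test_that("background base composition is near-uniform", {
  g <- gen_genome(gpa_scenario_spec(seed = 2))
  freq <- Biostrings::letterFrequency(g$genome[["chr1"]], c("A", "C", "G", "T"),
                                      as.prob = TRUE)
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("undersized chromosomes raise a sizing error", {
  expect_error(gpa_scenario_spec(chrom_length = 5e5), "sizing error")
  expect_error(gpa_scenario_spec(gene_classes = c(neuronal_common = 1L, hc_only = 1L,
                                                  neuronal_only = 1L, downregulated = 1L,
                                                  background = 1L)),
               "sum to")
})

test_that("cobind_fraction controls shared summits between co-binder and partner", {
  sc0 <- simulate_gpa_scenario(gpa_scenario_spec(seed = 5, cobind_fraction = 0))
  g0 <- sc0$peaks[sc0$peaks$tf == "G", ]
  a0 <- sc0$peaks[sc0$peaks$tf == "A" & sc0$peaks$condition == "GPA", ]
  expect_equal(sum(g0$summit %in% a0$summit), 0L)
  expect_false(any(sc0$truth$peaks$role == "cobound"))

  sc1 <- simulate_gpa_scenario(gpa_scenario_spec(seed = 5, cobind_fraction = 1))
  t1 <- sc1$truth$peaks
  n_partner <- sum(t1$tf == "A" & t1$condition == "GPA")
  expect_equal(sum(t1$role == "cobound"), n_partner)
})

test_that("summit jitter is tightly concentrated around the intended site", {
  sc <- simulate_gpa_scenario(gpa_scenario_spec(seed = 6, peak_jitter_sd = 10))
  tr <- sc$truth$peaks
  dev <- abs(sc$peaks$summit[match(tr$name, sc$peaks$name)] - tr$intended_summit)
  expect_gte(mean(dev <= 40), 0.99)
})

test_that("counts follow the planted NB mean-variance relationship", {
  # many replicates of the reference condition: per-gene variance should
  # track mu + alpha mu^2
  spec <- gpa_scenario_spec(seed = 8, n_replicates = 40L, dispersion = 0.1)
  g <- gen_genome(spec)
  cts <- gen_counts(spec, g$annotation)
  m <- as.matrix(cts$counts[, grepl("^none_", names(cts$counts))])
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  ratio <- v / (mu + 0.1 * mu^2)
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("planted fold changes are echoed in the count means", {
  sc <- shared_scenario()
  tr <- sc$truth$genes
  m <- as.matrix(sc$counts[, -1])
  rownames(m) <- sc$counts$gene_id
  gpa <- rowMeans(m[, grepl("^GPA_", colnames(m))])
  none <- rowMeans(m[, grepl("^none_", colnames(m))])
  hc <- tr$gene_id[tr$class == "hc_only"]
  lr <- log2(gpa[hc] / none[hc])
  expect_lt(abs(mean(lr) - 3), 0.3)

  flat <- gpa_scenario_spec(seed = 9, fold_changes = c(neuronal_common = 0, hc_only = 0,
                                                       neuronal_only = 0, downregulated = 0,
                                                       background = 0))
  g <- gen_genome(flat)
  cts <- gen_counts(flat, g$annotation)
  m2 <- as.matrix(cts$counts[, -1])
  lr2 <- log2((rowMeans(m2[, 7:9]) + 0.5) / (rowMeans(m2[, 1:3]) + 0.5))
  expect_lt(abs(mean(lr2)), 0.1)
})

test_that("every emitted peak and gene appears exactly once in the truth", {
  sc <- shared_scenario()
  expect_setequal(sc$truth$peaks$name, sc$peaks$name)
  expect_equal(anyDuplicated(sc$truth$peaks$name), 0L)
  expect_setequal(sc$truth$genes$gene_id, sc$counts$gene_id)
  expect_equal(anyDuplicated(sc$truth$genes$gene_id), 0L)
})

test_that("planted motif instances are recovered by the scanner at threshold", {
  sc <- shared_scenario()
  tr <- sc$truth$peaks
  planted <- tr[!is.na(tr$motif_planted), ]
  hits <- scan_window(sc$peaks[sc$peaks$name %in% planted$name, ], sc$genome,
                      sc$spec$motifs)
  found <- dplyr::distinct(hits[, c("name", "motif")])
  joined <- dplyr::left_join(planted, found,
                             by = c(name = "name", motif_planted = "motif"),
                             keep = TRUE)
  expect_equal(sum(is.na(joined$motif)), 0L)
})

test_that("scenario files round-trip through write_scenario and read_scenario", {
  sc <- shared_scenario()
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  back <- read_scenario(dir)
  expect_identical(as.character(back$genome), as.character(sc$genome))
  ord <- order(back$peaks$name); ord0 <- order(sc$peaks$name)
  expect_equal(back$peaks$summit[ord], sc$peaks$summit[ord0])
  expect_equal(as.data.frame(back$counts), as.data.frame(sc$counts))
  expect_equal(sort(back$annotation$genes$gene_id), sort(sc$annotation$genes$gene_id))
})
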