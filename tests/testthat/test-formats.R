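test_that("narrowPeak reader applies the summit-offset and midpoint rules", {
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t500\tp1\t0\t.\t5\t3\t2\t50",
               "chr1\t100\t500\tp2\t0\t.\t5\t3\t2\t-1"), path)
  pk <- read_narrowpeak(path)
  expect_equal(pk$summit, c(150L, 300L))
  expect_equal(pk$start, c(100L, 100L))
})

test_that("narrowPeak reader rejects malformed files with line numbers", {
  short <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t500\tp1\t0\t.", short)
  expect_error(read_narrowpeak(short), "10 columns")

  bad_summit <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t500\tp1\t0\t.\t5\t3\t2\t50",
               "chr1\t100\t500\tp2\t0\t.\t5\t3\t2\t900"), bad_summit)
  expect_error(read_narrowpeak(bad_summit), "line 2")

  bad_num <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\tx\t500\tp1\t0\t.\t5\t3\t2\t50", bad_num)
  expect_error(read_narrowpeak(bad_num), "line 1")
})

test_that("narrowPeak round-trips preserve all fields on random fixtures", {
  set.seed(42)
  for (i in 1:5) {
    pk <- random_peaks(50, prefix = sprintf("rt%d_", i))
    pk$score <- sample(0:1000, 50, replace = TRUE)
    pk$signal <- round(runif(50, 0, 100), 3)
    pk$pval <- round(runif(50, 0, 50), 3)
    pk$qval <- round(runif(50, 0, 50), 3)
    path <- withr::local_tempfile(fileext = ".narrowPeak")
    write_narrowpeak(pk, path)
    back <- read_narrowpeak(path)
    expect_equal(as.data.frame(back[, names(pk)]), as.data.frame(pk))
  }
})

test_that("GTF coordinates convert to 0-based half-open with strand-aware TSS", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    "chrA\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id \"g1\";",
    "chrA\tsrc\texon\t1001\t1200\t.\t+\t.\tgene_id \"g1\";",
    "chrA\tsrc\tgene\t5001\t7000\t.\t-\t.\tgene_id \"g2\";"
  ), path)
  ann <- read_gene_models(path)
  g1 <- ann$genes[ann$genes$gene_id == "g1", ]
  g2 <- ann$genes[ann$genes$gene_id == "g2", ]
  expect_equal(c(g1$start, g1$end, g1$tss), c(1000L, 2000L, 1000L))
  expect_equal(c(g2$start, g2$end, g2$tss), c(5000L, 7000L, 6999L))
  # g2 lacks exon rows: gets a gene-spanning exon
  expect_equal(ann$exons$start[ann$exons$gene_id == "g2"], 5000L)
})

test_that("gene-model reader rejects duplicate ids and unknown strands", {
  dup <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("chrA\tsrc\tgene\t1\t100\t.\t+\t.\tgene_id \"g1\";",
               "chrA\tsrc\tgene\t201\t300\t.\t+\t.\tgene_id \"g1\";"), dup)
  expect_error(read_gene_models(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrA\t10\t100\tg1\t0\t?", bad)
  expect_error(read_gene_models(bad), "strand")
})

test_that("gene models round-trip through the GTF writer", {
  set.seed(7)
  ann <- random_annotation(30)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gene_models(ann, path)
  back <- read_gene_models(path)
  ord <- order(ann$genes$gene_id)
  ord2 <- order(back$genes$gene_id)
  expect_equal(as.data.frame(back$genes[ord2, names(ann$genes)]),
               as.data.frame(ann$genes[ord, ]), ignore_attr = TRUE)
})

test_that("count matrix reader validates and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t10\t20", "g2\t0\t5"), path)
  cts <- read_counts(path)
  expect_equal(cts$s2, c(20L, 5L))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "g1\t3.5"), bad)
  expect_error(read_counts(bad), "non-negative integer")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "g1\t-2"), neg)
  expect_error(read_counts(neg), "non-negative integer")

  rt <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cts, rt)
  expect_equal(as.data.frame(read_counts(rt)), as.data.frame(cts))
})

test_that("motif file parsing handles consensus and PWM records", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "# comment",
    "EBOX\tCAGCTG",
    ">pwm1 threshold=4.5",
    "0.97 0.01 0.01 0.01",
    "0.01 0.97 0.01 0.01",
    "0.01 0.01 0.97 0.01",
    "0.25 0.25 0.25 0.25"
  ), path)
  m <- read_motifs(path)
  expect_equal(m$name, c("EBOX", "pwm1"))
  expect_equal(m$consensus[1], "CAGCTG")
  expect_equal(nchar(m$consensus[1]), 6L)
  expect_equal(dim(m$pwm[[2]]), c(4L, 4L))
  expect_equal(m$threshold[2], 4.5)
})

test_that("motif file parsing rejects invalid records with line numbers", {
  bad_letter <- withr::local_tempfile(fileext = ".txt")
  writeLines("M1\tCAGXTG", bad_letter)
  expect_error(read_motifs(bad_letter), "invalid IUPAC")

  bad_sum <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">p1", "0.5 0.1 0.1 0.1", "0.25 0.25 0.25 0.25",
               "0.25 0.25 0.25 0.25", "0.25 0.25 0.25 0.25"), bad_sum)
  expect_error(read_motifs(bad_sum), "line 2")

  short <- withr::local_tempfile(fileext = ".txt")
  writeLines("M1\tCAG", short)
  expect_error(read_motifs(short), "length")
})

test_that("motif and GMT writers round-trip", {
  m <- gpa_default_motifs()
  path <- withr::local_tempfile(fileext = ".txt")
  write_motifs(m, path)
  back <- read_motifs(path)
  expect_equal(back$name, m$name)
  expect_equal(back$consensus, m$consensus)

  sets <- list(a = c("g1", "g2"), b = c("g3", "g4", "g5"))
  gp <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, gp)
  expect_equal(read_gmt(gp), sets)
})
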