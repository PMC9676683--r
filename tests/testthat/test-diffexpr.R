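make_counts <- function(m, genes = sprintf("g%02d", seq_len(nrow(m)))) {
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = genes), tibble::as_tibble(m))
}

test_that("size factors follow the median-of-ratios construction", {
  ident <- make_counts(cbind(s1 = c(10, 20, 40), s2 = c(10, 20, 40)))
  expect_equal(unname(size_factors(ident)), c(1, 1))

  doubled <- make_counts(cbind(s1 = c(10, 20, 40), s2 = c(20, 40, 80)))
  expect_equal(unname(size_factors(doubled)), c(1 / sqrt(2), sqrt(2)))

  all_zero_row <- make_counts(cbind(s1 = c(0, 5), s2 = c(0, 5)))
  expect_equal(unname(size_factors(all_zero_row)), c(1, 1))
  expect_error(size_factors(make_counts(cbind(s1 = c(0, 1), s2 = c(1, 0)))),
               "all counts > 0")
})

test_that("size factors are scale-equivariant and match DESeq2 up to scaling", {
  set.seed(21)
  m <- matrix(rnbinom(600, mu = 50, size = 10), ncol = 6)
  cts <- make_counts(m)
  f <- size_factors(cts)
  m2 <- m; m2[, 3] <- m2[, 3] * 4
  f2 <- size_factors(make_counts(m2))
  # before the geometric-mean normalization the third factor quadruples;
  # after it, the ratio to the others scales by 4
  expect_equal(unname(f2[3] / f2[1]), unname(4 * f[3] / f[1]), tolerance = 1e-10)

  # identical up to one global rescaling (DESeq2 takes the median of log
  # ratios, which differs minutely from the ratio median at even gene counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(f / ref), rep(unname(f[1] / ref[1]), 6), tolerance = 1e-3)
})

test_that("NB Wald test handles degenerate genes and orders BH correctly", {
  set.seed(22)
  info <- tibble::tibble(sample = sprintf("s%d", 1:6),
                         condition = rep(c("t", "c"), each = 3))
  # constant-per-gene matrix: size factors are exactly 1, so a gene with
  # identical counts in every sample has log2FC 0
  const <- matrix(rep(c(0L, 50L, 10L, 200L), 6), ncol = 6)
  de0 <- nb_wald_test(make_counts(const, genes = sprintf("c%d", 1:4)), info,
                      c("t", "c"))
  expect_true(de0$all_zero[1])
  expect_equal(de0$pvalue[1], 1)
  expect_equal(de0$log2fc, rep(0, 4))

  m <- matrix(rnbinom(200 * 6, mu = 80, size = 10), ncol = 6)
  cts <- make_counts(m, genes = sprintf("g%03d", 1:200))
  de <- nb_wald_test(cts, info, c("t", "c"))
  expect_true(all(de$padj >= de$pvalue))
  expect_true(all(de$padj <= 1))
  # BH is a monotone step function of the raw p rank
  ord <- order(de$pvalue)
  expect_true(all(diff(de$padj[ord]) >= -1e-12))

  expect_error(nb_wald_test(cts, info[c(1, 4, 5), ], c("t", "c")), ">= 2 replicates")
})

test_that("DE selection uses inclusive thresholds with a strict option", {
  de <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                       log2fc = c(2, 1, 1.5, -2),
                       padj = c(0.01, 0.001, 0.04, 0.02))
  sel <- select_de(de)
  expect_setequal(sel$gene_id, c("a", "c", "d"))
  expect_equal(sel$direction[sel$gene_id == "a"], "up")
  expect_equal(sel$direction[sel$gene_id == "d"], "down")
  expect_false("b" %in% sel$gene_id)
  # boundary gene drops out under strict inequalities
  expect_false("c" %in% select_de(de, strict = TRUE)$gene_id)
})

test_that("PAM clustering is exact on planted profiles and degenerate k", {
  set.seed(23)
  prof <- rbind(matrix(rnorm(40 * 3, mean = rep(c(5, 5, 0), each = 40), sd = 0.2), ncol = 3),
                matrix(rnorm(40 * 3, mean = rep(c(5, 0, 0), each = 40), sd = 0.2), ncol = 3))
  mm <- dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%02d", 1:80)),
                         tibble::as_tibble(prof, .name_repair = ~c("c1", "c2", "c3")))
  cl <- cluster_de(mm, k = 2)
  truth <- rep(1:2, each = 40)
  expect_equal(mclust::adjustedRandIndex(cl$assignments$cluster, truth), 1)
  expect_true(all(cl$medoids %in% cl$assignments$gene_id))

  one <- cluster_de(mm, k = 1)
  expect_equal(unique(one$assignments$cluster), 1L)
  expect_error(cluster_de(mm[1:3, ], k = 5), "exceeds")
})

test_that("PAM label assignment is equivariant under row swaps", {
  set.seed(24)
  x <- rbind(matrix(rnorm(30, 0, 0.3), ncol = 3),
             matrix(rnorm(30, 4, 0.3), ncol = 3))
  ids <- sprintf("g%02d", 1:20)
  mm <- dplyr::bind_cols(tibble::tibble(gene_id = ids),
                         tibble::as_tibble(x, .name_repair = ~c("a", "b", "c")))
  cl1 <- cluster_de(mm, k = 2, standardize = FALSE)
  perm <- c(20:1)
  cl2 <- cluster_de(mm[perm, ], k = 2, standardize = FALSE)
  lab1 <- setNames(cl1$assignments$cluster, cl1$assignments$gene_id)
  lab2 <- setNames(cl2$assignments$cluster, cl2$assignments$gene_id)
  expect_equal(mclust::adjustedRandIndex(lab1[ids], lab2[ids]), 1)
})

test_that("PAM objective never increases across SWAP iterations and matches cluster::pam", {
  set.seed(25)
  x <- matrix(rnorm(60 * 4), ncol = 4)
  fit <- pam_kmedoids(x, 4)
  expect_true(all(diff(fit$objective_trace) <= 1e-12))

  ref <- cluster::pam(x, 4, metric = "euclidean", do.swap = TRUE)
  ref_obj <- sum(apply(as.matrix(dist(x))[, ref$id.med, drop = FALSE], 1, min))
  expect_lte(fit$objective, ref_obj * 1.02)

  sep <- rbind(matrix(rnorm(30, 0, 0.2), ncol = 3),
               matrix(rnorm(30, 5, 0.2), ncol = 3),
               matrix(rnorm(30, 10, 0.2), ncol = 3))
  ours <- pam_kmedoids(sep, 3)
  theirs <- cluster::pam(sep, 3)$clustering
  expect_equal(mclust::adjustedRandIndex(ours$cluster, theirs), 1)
})

test_that("subclustering splits one primary cluster into lettered labels", {
  set.seed(26)
  x <- rbind(matrix(rnorm(60, mean = rep(c(0, 5, 5), each = 20), sd = 0.2), ncol = 3),
             matrix(rnorm(60, mean = rep(c(0, 5, 0), each = 20), sd = 0.2), ncol = 3),
             matrix(rnorm(60, mean = rep(c(5, 0, 0), each = 20), sd = 0.2), ncol = 3))
  mm <- dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%02d", 1:60)),
                         tibble::as_tibble(x, .name_repair = ~c("a", "b", "c")))
  cl <- cluster_de(mm, k = 2, subcluster = list(cluster = 1, k = 2))
  labs <- cl$assignments$label
  # whichever primary cluster is "1", it must now carry A/B suffixes
  expect_true(any(grepl("^C-1A$", labs)) && any(grepl("^C-1B$", labs)))
  expect_false(any(labs == "C-1"))
})

test_that("condition means normalize by size factors", {
  cts <- make_counts(cbind(s1 = c(10, 30), s2 = c(20, 60)))
  info <- tibble::tibble(sample = c("s1", "s2"), condition = c("x", "y"))
  cm <- condition_means(cts, info)
  # columns differ only by depth: normalized means must agree
  expect_equal(cm$x, cm$y)
})
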