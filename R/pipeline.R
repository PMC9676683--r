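# End-to-end orchestration: differential expression -> peak algebra ->
# annotation -> motifs -> direction analysis -> GSEA, on an in-memory
# scenario or on files written by write_scenario(). Every tunable lives in
# pipeline_params() and is echoed into the report's provenance block.

#' Pipeline tunables
#'
#' @param w Summit-window width for overlap classification (bp).
#' @param tss_window Half-width for peak-to-cluster association (bp).
#' @param motif_halfwidth Motif scan half-width around summits (bp).
#' @param promoter_window Promoter definition around the TSS (bp, oriented).
#' @param downstream Downstream feature extent past gene end (bp).
#' @param lfc_min,fdr DE selection thresholds.
#' @param strict_de Use strict instead of inclusive DE thresholds.
#' @param cluster_k Primary number of expression clusters.
#' @param subcluster_k Second-level k used to split the largest primary
#'   cluster (`NULL` to skip).
#' @param bandwidth,halfspan Gaussian bandwidth and span of the
#'   distance-direction curves (bp).
#' @param n_perm Gene-set permutations for the GSEA stage.
#' @param gsea_metric Ranking metric, `"s2n"` or `"log2fc"`.
#' @param seed Seed for the permutation stage.
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(w = 300L, tss_window = 5000L, motif_halfwidth = 125L,
                            promoter_window = c(-3000L, 3000L), downstream = 3000L,
                            lfc_min = 1.5, fdr = 0.05, strict_de = FALSE,
                            cluster_k = 4L, subcluster_k = 2L,
                            bandwidth = 2000, halfspan = 30000, n_perm = 1000L,
                            gsea_metric = "s2n", seed = 1L) {
  params <- structure(
    list(w = w, tss_window = tss_window, motif_halfwidth = motif_halfwidth,
         promoter_window = promoter_window, downstream = downstream,
         lfc_min = lfc_min, fdr = fdr, strict_de = strict_de,
         cluster_k = cluster_k, subcluster_k = subcluster_k,
         bandwidth = bandwidth, halfspan = halfspan, n_perm = n_perm,
         gsea_metric = gsea_metric, seed = seed),
    class = "pipeline_params"
  )
  validate_pipeline_params(params)
}

#' @rdname pipeline_params
#' @param params A `pipeline_params` list.
#' @export
validate_pipeline_params <- function(params) {
  for (fld in c("w", "tss_window", "motif_halfwidth", "downstream", "lfc_min",
                "fdr", "cluster_k", "bandwidth", "halfspan", "n_perm")) {
    assert_scalar_number(params[[fld]], fld, positive = TRUE)
  }
  if (length(params$promoter_window) != 2L ||
      params$promoter_window[1] > params$promoter_window[2]) {
    abort("`promoter_window` must be c(lower, upper)")
  }
  if (!params$gsea_metric %in% c("s2n", "log2fc")) {
    abort("`gsea_metric` must be 's2n' or 'log2fc'")
  }
  params
}

#' Read scenario inputs back from a directory
#'
#' Reads the files written by [write_scenario()] (genome FASTA, GTF,
#' `{tf}_{condition}.narrowPeak` files, counts, motifs, truth tables when
#' present) and validates that every file refers to the same chromosome
#' names; a mismatch is a hard error naming the files.
#'
#' @param dir Directory holding the scenario files.
#' @return A `gpa_scenario`-shaped list usable by [run_gpa_pipeline()].
#' @export
read_scenario <- function(dir) {
  genome <- read_fasta(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  annotation <- read_gene_models(file.path(dir, "genes.gtf"),
                                 chrom_lengths = setNames(Biostrings::width(genome),
                                                          names(genome)))
  np <- list.files(dir, pattern = "\\.narrowPeak$", full.names = TRUE)
  if (!length(np)) abort(sprintf("%s: no narrowPeak files", dir))
  peaks <- bind_rows(lapply(np, function(path) {
    parts <- strsplit(sub("\\.narrowPeak$", "", basename(path)), "_")[[1]]
    pk <- read_narrowpeak(path)
    pk$tf <- parts[1]
    pk$condition <- paste(parts[-1], collapse = "_")
    pk
  }))
  for (what in list(c("genes.gtf", paste(unique(annotation$genes$chrom), collapse = ",")),
                    c("narrowPeak", paste(unique(peaks$chrom), collapse = ",")))) {
    bad <- setdiff(strsplit(what[2], ",")[[1]], names(genome))
    if (length(bad)) {
      abort(sprintf("chromosome mismatch: %s uses %s absent from genome.fa",
                    what[1], paste(bad, collapse = ", ")))
    }
  }
  counts <- read_counts(file.path(dir, "counts.tsv"))
  sample_info <- tibble(
    sample = setdiff(names(counts), "gene_id"),
    condition = sub("_r[0-9]+$", "", setdiff(names(counts), "gene_id"))
  )
  truth <- NULL
  tp <- file.path(dir, "truth_peaks.tsv"); tg <- file.path(dir, "truth_genes.tsv")
  if (file.exists(tp) && file.exists(tg)) {
    truth <- list(peaks = readr::read_tsv(tp, show_col_types = FALSE, progress = FALSE),
                  genes = readr::read_tsv(tg, show_col_types = FALSE, progress = FALSE))
  }
  motifs <- if (file.exists(file.path(dir, "motifs.txt"))) {
    read_motifs(file.path(dir, "motifs.txt"))
  } else gpa_default_motifs()
  structure(
    list(spec = NULL, genome = genome, annotation = annotation, peaks = peaks,
         counts = counts, sample_info = sample_info, truth = truth, motifs = motifs),
    class = "gpa_scenario"
  )
}

peak_set <- function(scenario, tf, condition) {
  pk <- scenario$peaks[scenario$peaks$tf == tf & scenario$peaks$condition == condition, ]
  if (!nrow(pk)) abort(sprintf("no peaks for %s in condition %s", tf, condition))
  pk
}

#' Run the full analysis on a scenario
#'
#' Stages run in dependency order (differential expression, peak-set
#' algebra, annotation, motifs, direction analysis, GSEA); a failure stops
#' the run with a stage-labelled error. The report is deterministic for a
#' fixed scenario and parameter set.
#'
#' @param scenario A `gpa_scenario` from [simulate_gpa_scenario()] or
#'   [read_scenario()].
#' @param params A [pipeline_params()].
#' @return A `gpa_report`: named list of stage outputs plus a `provenance`
#'   block (parameters, seed, package version, input sizes).
#' @export
run_gpa_pipeline <- function(scenario, params = pipeline_params()) {
  params <- validate_pipeline_params(params)
  stopifnot(inherits(scenario, "gpa_scenario"))
  motifs <- scenario$motifs %||% scenario$spec$motifs
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  de <- stage("diffexpr", {
    conds <- setdiff(unique(scenario$sample_info$condition), "none")
    tests <- lapply(conds, function(cd) {
      nb_wald_test(scenario$counts, scenario$sample_info, c(cd, "none"))
    })
    names(tests) <- conds
    selected <- lapply(tests, select_de, lfc_min = params$lfc_min, fdr = params$fdr,
                       strict = params$strict_de)
    de_genes <- sort(unique(unlist(lapply(selected, function(s) s$gene_id))))
    cm <- condition_means(scenario$counts, scenario$sample_info)
    clusters <- NULL
    if (length(de_genes) >= params$cluster_k) {
      mm <- cm[cm$gene_id %in% de_genes, ]
      cl0 <- cluster_de(mm, k = params$cluster_k, standardize = TRUE)
      sub <- NULL
      if (!is.null(params$subcluster_k)) {
        largest <- as.integer(names(which.max(table(cl0$assignments$cluster))))
        sub <- list(cluster = largest, k = params$subcluster_k)
      }
      clusters <- cluster_de(mm, k = params$cluster_k, subcluster = sub,
                             standardize = TRUE)
    }
    list(tests = tests, selected = selected, de_genes = de_genes,
         condition_means = cm, clusters = clusters)
  })

  algebra <- stage("peakalgebra", {
    chrlen <- scenario$annotation$chrom_lengths
    pair <- classify_pair(peak_set(scenario, "A", "A"),
                          peak_set(scenario, "A", "GPA"),
                          w = params$w, set_names = c("A", "GPA"),
                          chrom_lengths = chrlen)
    part_gpa <- membership_partition(
      list(G = peak_set(scenario, "G", "GPA"),
           P = peak_set(scenario, "P", "GPA"),
           A = peak_set(scenario, "A", "GPA")),
      w = params$w, chrom_lengths = chrlen
    )
    part_atoh <- membership_partition(
      list(A_alone = peak_set(scenario, "A", "A"),
           A_gpa = peak_set(scenario, "A", "GPA"),
           P_gpa = peak_set(scenario, "P", "GPA")),
      w = params$w, chrom_lengths = chrlen
    )
    list(pair = pair, pair_counts = attr(pair, "counts"),
         partition_gpa = part_gpa, partition_gpa_counts = partition_counts(part_gpa),
         partition_atoh = part_atoh, partition_atoh_counts = partition_counts(part_atoh))
  })

  ann <- stage("annotate", {
    assignments <- nearest_tss(scenario$peaks, scenario$annotation)
    gpeaks <- peak_set(scenario, "G", "GPA")
    features <- genomic_features(gpeaks, scenario$annotation,
                                 promoter_window = params$promoter_window,
                                 downstream = params$downstream)
    assoc <- NULL
    if (!is.null(de$clusters)) {
      grp <- algebra$pair
      grp$group <- grp$membership
      assoc <- cluster_association(grp, de$clusters, scenario$annotation,
                                   window = params$tss_window)
    }
    list(assignments = assignments, features = features, cluster_assoc = assoc)
  })

  mot <- stage("motifs", {
    hits <- scan_window(scenario$peaks, scenario$genome, motifs,
                        halfwidth = params$motif_halfwidth)
    pair_groups <- tibble(name = algebra$pair$name, group = algebra$pair$membership)
    ebox_counts <- counts_per_peak(hits, scenario$peaks, motif = "ebox")
    histogram <- motif_histogram(ebox_counts, pair_groups)
    gpeaks <- peak_set(scenario, "G", "GPA")
    ghits <- hits[hits$name %in% gpeaks$name, ]
    positional <- positional_distribution(ghits, n_peaks = nrow(gpeaks),
                                          halfwidth = params$motif_halfwidth,
                                          motif_names = motifs$name)
    classes <- partition_by_motif(gpeaks, ghits, own_motif = "gfi1",
                                  ebox_motif = "ebox")
    list(hits = hits, ebox_histogram = histogram, positional = positional,
         motif_classes = classes)
  })

  direction <- stage("regdir", {
    de_sel <- de$selected[["GPA"]]
    if (is.null(de_sel)) abort("no GPA contrast available")
    fr <- direction_fractions(ann$assignments, de_sel, mot$motif_classes)
    curves <- distance_direction_curve(ann$assignments, de_sel, mot$motif_classes,
                                       halfspan = params$halfspan,
                                       bandwidth = params$bandwidth)
    list(fractions = fr, curves = curves)
  })

  gsea <- stage("gsea", {
    if (is.null(de$clusters)) return(NULL)
    sf <- size_factors(scenario$counts)
    norm <- scenario$counts
    for (smp in names(sf)) norm[[smp]] <- norm[[smp]] / sf[[smp]]
    ranked <- rank_genes(norm, scenario$sample_info, c("GPA", "none"),
                         metric = params$gsea_metric)
    labs <- de$clusters$assignments
    sets <- split(labs$gene_id, labs$label)
    sets <- sets[lengths(sets) >= 5L]
    res <- nes_fdr(ranked, sets, n_perm = params$n_perm, seed = params$seed)
    list(ranked = ranked, results = res)
  })

  structure(
    list(de = de, algebra = algebra, annotate = ann, motifs = mot,
         direction = direction, gsea = gsea,
         provenance = list(
           params = unclass(params),
           package_version = as.character(utils::packageVersion("peakcross")),
           n_peaks = nrow(scenario$peaks), n_genes = nrow(scenario$annotation$genes),
           n_samples = nrow(scenario$sample_info),
           params_hash = rlang::hash(unclass(params))
         )),
    class = "gpa_report"
  )
}

#' @export
print.gpa_report <- function(x, ...) {
  cat("<gpa_report>\n")
  cat(sprintf("  DE genes: %d; clusters: %s\n", length(x$de$de_genes),
              if (is.null(x$de$clusters)) "none"
              else paste(sort(unique(x$de$clusters$assignments$label)), collapse = ", ")))
  cat(sprintf("  pair classes: %s\n",
              paste(sprintf("%s=%d", x$algebra$pair_counts$membership,
                            x$algebra$pair_counts$n), collapse = ", ")))
  invisible(x)
}

#' Recovery of planted structure from a pipeline report
#'
#' Compares the report against the scenario's ground truth: the fraction of
#' recruiter-dependent peaks classed condition-unique, the fraction of
#' co-binder peaks sharing a merged region with the partner TF, the
#' direction fractions of the own-motif and E-box motif classes, and the
#' adjusted Rand index between recovered and planted expression clusters.
#'
#' @param report A `gpa_report`.
#' @param truth The scenario's `truth` list (`peaks`, `genes`).
#' @return Tibble `metric`, `value`, `n`.
#' @export
scenario_recovery <- function(report, truth) {
  stopifnot(inherits(report, "gpa_report"))
  tp <- truth$peaks
  pair <- report$algebra$pair
  if (!all(tp$name[tp$tf == "A"] %in% pair$name)) {
    abort("truth/report peak id mismatch")
  }

  memb <- setNames(pair$membership, pair$name)
  recruited <- tp$name[tp$role == "recruited"]
  recruited_unique <- mean(memb[recruited] == "GPA_unique")
  retained <- tp$name[tp$role == "retained"]
  retained_common <- if (length(retained)) mean(memb[retained] == "common") else NA_real_

  contrib <- tidy(report$algebra$partition_gpa)
  cobound <- tp$name[tp$role == "cobound"]
  with_a <- contrib$name[vapply(strsplit(contrib$members, "\\+"),
                                function(m) "A" %in% m, TRUE)]
  cobound_common <- if (length(cobound)) mean(cobound %in% with_a) else NA_real_

  fr <- report$direction$fractions
  frac_of <- function(cls, dir) {
    v <- fr$fraction[fr$level == "peak" & fr$motif_class == cls & fr$direction == dir]
    if (length(v)) v else NA_real_
  }
  own_down <- frac_of("own_only", "down")
  ebox_up <- frac_of("ebox_containing", "up")

  ari <- NA_real_; n_cl <- 0L
  if (!is.null(report$de$clusters)) {
    rec <- report$de$clusters$assignments[, c("gene_id", "label")]
    planted <- rename(truth$genes[, c("gene_id", "cluster")], planted = "cluster")
    both <- inner_join(rec, planted, by = "gene_id") |>
      filter(!is.na(.data$planted))
    if (nrow(both)) {
      ari <- mclust::adjustedRandIndex(both$label, both$planted)
      n_cl <- nrow(both)
    }
  }

  tibble(
    metric = c("recruited_unique_frac", "retained_common_frac", "cobound_common_frac",
               "own_motif_down_frac", "ebox_up_frac", "cluster_ari"),
    value = c(recruited_unique, retained_common, cobound_common,
              own_down, ebox_up, ari),
    n = c(length(recruited), length(retained), length(cobound),
          sum(fr$n[fr$level == "peak" & fr$motif_class == "own_only"]),
          sum(fr$n[fr$level == "peak" & fr$motif_class == "ebox_containing"]),
          n_cl)
  )
}
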