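# Synthetic GPA scenario generator: a "default" TF (A) bound at neuronal
# gene classes, a "recruiter" TF (P) that redirects A to a hair-cell-like
# class, and a co-binder (G) that sits on A's summits without its own motif
# there plus own-motif promoter peaks at a repressed gene class. Every
# emitted peak and gene carries a ground-truth label.

GPA_CONDITIONS <- c("none", "A", "GPA")

#' Default motif models for the GPA scenario
#'
#' Synthetic stand-ins, not the published matrices: an E-box core with a 5'
#' A preference (AtEAM-like), an AT-rich POU-homeodomain-type consensus, and
#' an AATC-core Gfi1-type consensus. Editable: any motif tibble in
#' [read_motifs()] layout works.
#'
#' @return A motif tibble (`name`, `kind`, `consensus`, ...).
#' @export
gpa_default_motifs <- function() {
  tibble(
    name = c("ebox", "pou4f", "gfi1"),
    kind = "consensus",
    consensus = c("ACAGCTG", "ATAATTAAT", "AAATCACTGC"),
    max_mismatch = 0L,
    pwm = list(NULL, NULL, NULL),
    threshold = NA_real_
  )
}

gpa_default_recruitment <- function() {
  tibble(
    tf        = c("A", "A", "A", "A", "P", "G"),
    condition = c("A", "A", "GPA", "GPA", "GPA", "GPA"),
    class     = c("neuronal_common", "neuronal_only", "neuronal_common",
                  "hc_only", "hc_only", "downregulated"),
    role      = c("default", "default", "retained", "recruited",
                  "recruiter", "own_promoter"),
    plant_motif = TRUE,
    summit_offset = c(500L, 500L, 500L, 500L, 560L, 500L)
  )
}

#' Specify a synthetic GPA scenario
#'
#' Defaults encode the study design the package is built around: three
#' expression conditions (uninduced reference `none`, default factor alone
#' `A`, full combination `GPA`), five gene classes whose planted fold
#' changes reproduce a five-group expression-cluster structure
#' (C-1A up in both induced conditions, C-1B up mainly in `A`, C-2 up only
#' in `GPA`, C-3/C-4 down in one condition each), condition-dependent TF
#' binding with motif instances written under the summits, and a co-binder
#' placed on half of the partner's summits without its own motif there.
#'
#' @param n_chroms,chrom_length Number of chromosomes and length of each (bp).
#' @param n_genes Total genes, split evenly across chromosomes.
#' @param gene_classes Named counts over the five classes
#'   `neuronal_common`, `hc_only`, `neuronal_only`, `downregulated`,
#'   `background`; must sum to `n_genes`.
#' @param motif_set Named map TF -> motif name; motifs themselves in `motifs`.
#' @param motifs Motif tibble holding the referenced models.
#' @param recruitment_table Tibble (`tf`, `condition`, `class`, `role`,
#'   `plant_motif`, `summit_offset`) saying which TF binds which gene class
#'   in which condition.
#' @param cobind_fraction Fraction of the default TF's `GPA` summits copied
#'   by the co-binder G (no own motif planted there).
#' @param peak_jitter_sd SD (bp) of Gaussian jitter on summit placement.
#' @param peak_halfwidth Peak interval is summit +/- this many bp.
#' @param n_replicates Replicates per condition in the count matrix.
#' @param fold_changes Named log2 effects per gene class (sign included).
#' @param dispersion Negative-binomial dispersion alpha (var = mu + alpha mu^2).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-gene
#'   baseline means.
#' @param seed Integer seed; every generator derives its stream from it.
#' @return A `scenario_spec` list.
#' @export
gpa_scenario_spec <- function(n_chroms = 2L,
                              chrom_length = 1e6,
                              n_genes = 200L,
                              gene_classes = c(neuronal_common = 25L, hc_only = 25L,
                                               neuronal_only = 20L, downregulated = 20L,
                                               background = 110L),
                              motif_set = c(A = "ebox", P = "pou4f", G = "gfi1"),
                              motifs = gpa_default_motifs(),
                              recruitment_table = gpa_default_recruitment(),
                              cobind_fraction = 0.5,
                              peak_jitter_sd = 20,
                              peak_halfwidth = 200L,
                              n_replicates = 3L,
                              fold_changes = c(neuronal_common = 3, hc_only = 3,
                                               neuronal_only = 3, downregulated = -3,
                                               background = 0),
                              dispersion = 0.05,
                              baseline_meanlog = log(100),
                              baseline_sdlog = 0.5,
                              seed = 1L) {
  spec <- structure(
    list(n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
         n_genes = as.integer(n_genes), gene_classes = gene_classes,
         motif_set = motif_set, motifs = motifs,
         recruitment_table = as_tibble(recruitment_table),
         cobind_fraction = cobind_fraction, peak_jitter_sd = peak_jitter_sd,
         peak_halfwidth = as.integer(peak_halfwidth),
         n_replicates = as.integer(n_replicates), fold_changes = fold_changes,
         dispersion = dispersion, baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog, seed = as.integer(seed)),
    class = "scenario_spec"
  )
  validate_scenario_spec(spec)
}

#' @rdname gpa_scenario_spec
#' @param spec A `scenario_spec`.
#' @export
validate_scenario_spec <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  for (fld in c("n_chroms", "chrom_length", "n_genes", "n_replicates", "peak_halfwidth")) {
    assert_scalar_number(spec[[fld]], fld, positive = TRUE)
  }
  assert_scalar_number(spec$dispersion, "dispersion", positive = TRUE)
  if (spec$cobind_fraction < 0 || spec$cobind_fraction > 1) {
    abort("`cobind_fraction` must be in [0, 1]")
  }
  if (any(spec$gene_classes < 0) || sum(spec$gene_classes) != spec$n_genes) {
    abort("`gene_classes` counts must be non-negative and sum to `n_genes`")
  }
  genes_per_chrom <- ceiling(spec$n_genes / spec$n_chroms)
  if (spec$chrom_length < 10 * genes_per_chrom * 1000) {
    abort(sprintf(paste0("sizing error: chrom_length %d cannot hold %d genes per ",
                         "chromosome (need >= %d)"),
                  spec$chrom_length, genes_per_chrom, 10 * genes_per_chrom * 1000))
  }
  missing_m <- setdiff(unname(spec$motif_set), spec$motifs$name)
  if (length(missing_m)) {
    abort(sprintf("motif_set references missing motif(s): %s",
                  paste(missing_m, collapse = ", ")))
  }
  spec
}

#' Generate the synthetic genome and gene models
#'
#' Background sequence is i.i.d. uniform over A/C/G/T. Genes are laid out
#' on non-overlapping slots (one gene per ~`chrom_length / genes_per_chrom`
#' bp) with 50/50 strand, two terminal exons and an intron, and class labels
#' drawn without replacement. TSS is `start` on `+` and `end - 1` on `-`.
#'
#' @param spec A [gpa_scenario_spec()].
#' @return List with `genome` (a `DNAStringSet`) and `annotation`
#'   (a [genome_annotation()] whose gene table carries a `class` column).
#' @export
gen_genome <- function(spec) {
  spec <- validate_scenario_spec(spec)
  set.seed(child_seed(spec$seed, "genome"))
  chroms <- sprintf("chr%d", seq_len(spec$n_chroms))
  seqs <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE),
          collapse = "")
  }, "")
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms

  chrom_of <- chroms[((seq_len(spec$n_genes) - 1L) %% spec$n_chroms) + 1L]
  idx_in_chrom <- stats::ave(seq_len(spec$n_genes), chrom_of, FUN = seq_along)
  genes_per_chrom <- max(table(chrom_of))
  slot <- spec$chrom_length %/% genes_per_chrom
  if (slot < 10000L) abort("sizing error: gene slots below 10 kb")

  len <- sample(800:1600, spec$n_genes, replace = TRUE)
  offset <- 4000L + sample(0:1000, spec$n_genes, replace = TRUE)
  start <- (idx_in_chrom - 1L) * slot + offset
  end <- start + len
  if (any(end > spec$chrom_length - 1000L)) abort("sizing error: gene exceeds chromosome")
  strand <- sample(c("+", "-"), spec$n_genes, replace = TRUE)
  class <- sample(rep(names(spec$gene_classes), times = spec$gene_classes))

  genes <- tibble(
    gene_id = sprintf("g%03d", seq_len(spec$n_genes)),
    chrom = chrom_of, start = as.integer(start), end = as.integer(end),
    strand = strand,
    tss = as.integer(ifelse(strand == "+", start, end - 1L)),
    class = class
  )
  exons <- bind_rows(
    tibble(gene_id = genes$gene_id, chrom = genes$chrom,
           start = genes$start, end = genes$start + 200L),
    tibble(gene_id = genes$gene_id, chrom = genes$chrom,
           start = genes$end - 200L, end = genes$end)
  ) |> arrange(.data$gene_id, .data$start)

  ann <- genome_annotation(genes, exons = exons,
                           chrom_lengths = setNames(rep(spec$chrom_length, spec$n_chroms),
                                                    chroms))
  list(genome = genome, annotation = ann)
}

# Replace one degenerate IUPAC consensus with a concrete instance.
concretize_consensus <- function(consensus) {
  letters <- strsplit(consensus, "")[[1]]
  paste(vapply(letters, function(l) {
    opts <- strsplit(IUPAC_CODES[[l]], "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, ""), collapse = "")
}

#' Generate per-TF/condition peak sets and plant motif instances
#'
#' One peak per (TF, condition, target gene of the bound class), summit
#' placed upstream of the TSS in gene orientation with Gaussian jitter.
#' For motif-binding TFs a concrete motif instance is written into the
#' genome in place (no insertions) within +/-40 bp of the intended summit;
#' a TF binding the same gene in two conditions reuses one instance. The
#' co-binder copies `cobind_fraction` of the default TF's `GPA` summits
#' without planting its own motif there.
#'
#' @param spec A [gpa_scenario_spec()].
#' @param genome,annotation Output of [gen_genome()].
#' @return List with `peaks` (peak tibble with `tf`, `condition` columns),
#'   the modified `genome`, and `truth` (per-peak tibble: `name`, `tf`,
#'   `condition`, `gene_id`, `class`, `role`, `motif_planted`,
#'   `intended_summit`).
#' @export
gen_peaks <- function(spec, genome, annotation) {
  spec <- validate_scenario_spec(spec)
  set.seed(child_seed(spec$seed, "peaks"))
  genes <- annotation$genes
  halfw <- spec$peak_halfwidth
  scan_halfwidth <- 125L
  for (tf in names(spec$motif_set)) {
    m <- spec$motifs[spec$motifs$name == spec$motif_set[[tf]], ]
    if (m$kind == "consensus" && nchar(m$consensus) > 2L * scan_halfwidth) {
      abort(sprintf("config error: motif '%s' longer than the scan window", m$name))
    }
  }

  plant_registry <- list()   # key "tf|gene" -> list(pos, instance)
  occupied <- list()         # per chrom: matrix-free list of c(start, end)
  peaks <- list(); truths <- list()

  plant_instance <- function(tf, gene_row, intended) {
    key <- paste(tf, gene_row$gene_id, sep = "|")
    if (!is.null(plant_registry[[key]])) return(plant_registry[[key]])
    motif <- spec$motifs[spec$motifs$name == spec$motif_set[[tf]], ]
    inst <- concretize_consensus(motif$consensus)
    len <- nchar(inst)
    occ <- occupied[[gene_row$chrom]] %||% list()
    pos <- NA_integer_
    for (try in 1:50) {
      cand <- intended - len %/% 2L + sample(-40:40, 1L)
      clash <- any(vapply(occ, function(iv) cand < iv[2] && cand + len > iv[1], TRUE))
      if (!clash) { pos <- cand; break }
    }
    if (is.na(pos)) abort("could not place motif instance without overlap")
    rec <- list(pos = pos, instance = inst, motif = motif$name)
    plant_registry[[key]] <<- rec
    occupied[[gene_row$chrom]] <<- c(occ, list(c(pos, pos + len)))
    rec
  }

  add_peaks <- function(tf, condition, target, role, plant, offsets = NULL,
                        summit_offset = 500L, copy_summits = NULL) {
    n <- nrow(target)
    if (!n) return(invisible(NULL))
    if (is.null(copy_summits)) {
      intended <- ifelse(target$strand == "+",
                         target$tss - summit_offset, target$tss + summit_offset)
      summit <- as.integer(round(intended + rnorm(n, 0, spec$peak_jitter_sd)))
    } else {
      intended <- copy_summits
      summit <- as.integer(copy_summits)
    }
    planted <- rep(NA_character_, n)
    if (plant) {
      for (i in seq_len(n)) {
        rec <- plant_instance(tf, target[i, ], as.integer(intended[i]))
        planted[i] <- rec$motif
        genome[[target$chrom[i]]] <<- Biostrings::replaceLetterAt(
          genome[[target$chrom[i]]],
          at = seq(rec$pos + 1L, rec$pos + nchar(rec$instance)),
          letter = rec$instance
        )
      }
    }
    nm <- sprintf("%s_%s_%03d", tf, condition, seq_len(n) + length(peaks) * 0L +
                    sum(vapply(peaks, nrow, 0L)))
    pk <- tibble(
      tf = tf, condition = condition, chrom = target$chrom,
      start = summit - halfw, end = summit + halfw, name = nm,
      score = sample(100:1000, n, replace = TRUE), strand = ".",
      signal = round(runif(n, 5, 50), 3), pval = round(runif(n, 5, 100), 3),
      qval = round(runif(n, 2, 50), 3), summit = summit
    )
    peaks[[length(peaks) + 1L]] <<- pk
    truths[[length(truths) + 1L]] <<- tibble(
      name = nm, tf = tf, condition = condition, gene_id = target$gene_id,
      class = target$class, role = role, motif_planted = planted,
      intended_summit = as.integer(intended)
    )
    invisible(NULL)
  }

  eff <- gene_effects(spec, genes)
  for (i in seq_len(nrow(spec$recruitment_table))) {
    row <- spec$recruitment_table[i, ]
    target <- genes[genes$class == row$class, ]
    if (row$role == "own_promoter") {
      # a repressor's own-motif promoter peaks sit at the genes it actually
      # represses in the condition where it is expressed
      lfc_col <- paste0("lfc_", row$condition)
      affected <- eff$gene_id[eff[[lfc_col]] != 0]
      target <- target[target$gene_id %in% affected, ]
    }
    add_peaks(row$tf, row$condition, target, row$role, row$plant_motif,
              summit_offset = row$summit_offset)
  }

  # Co-binder G copies a fraction of A's GPA summits (no own motif there).
  all_pk <- bind_rows(peaks); all_tr <- bind_rows(truths)
  partner <- which(all_pk$tf == "A" & all_pk$condition == "GPA")
  n_cob <- round(spec$cobind_fraction * length(partner))
  if (n_cob > 0) {
    sel <- sort(sample(partner, n_cob))
    tgt <- genes[match(all_tr$gene_id[sel], genes$gene_id), ]
    add_peaks("G", "GPA", tgt, "cobound", plant = FALSE,
              copy_summits = all_pk$summit[sel])
  }

  peaks <- validate_peaks(bind_rows(peaks))
  truth <- bind_rows(truths)
  stopifnot(!anyDuplicated(truth$name))
  list(peaks = peaks, genome = genome, truth = truth)
}

# Per-gene log2 fold change for each induced condition, from class patterns.
# downregulated genes alternate between a down-in-A half (C-3 analog) and a
# down-in-GPA half (C-4 analog).
gene_effects <- function(spec, genes) {
  fc <- spec$fold_changes
  n <- nrow(genes)
  lfc_A <- numeric(n); lfc_GPA <- numeric(n)
  cls <- genes$class
  lfc_A[cls == "neuronal_common"] <- fc[["neuronal_common"]]
  lfc_GPA[cls == "neuronal_common"] <- fc[["neuronal_common"]]
  lfc_A[cls == "neuronal_only"] <- fc[["neuronal_only"]]
  lfc_GPA[cls == "neuronal_only"] <- fc[["neuronal_only"]] * 0.4
  lfc_GPA[cls == "hc_only"] <- fc[["hc_only"]]
  down <- which(cls == "downregulated")
  half <- down[seq_along(down) %% 2L == 1L]
  lfc_A[half] <- fc[["downregulated"]]
  lfc_GPA[setdiff(down, half)] <- fc[["downregulated"]]
  cluster <- dplyr::case_when(
    cls == "neuronal_common" ~ "C-1A",
    cls == "neuronal_only" ~ "C-1B",
    cls == "hc_only" ~ "C-2",
    genes$gene_id %in% genes$gene_id[half] ~ "C-3",
    cls == "downregulated" ~ "C-4",
    TRUE ~ NA_character_
  )
  tibble(gene_id = genes$gene_id, class = cls, cluster = cluster,
         lfc_A = lfc_A, lfc_GPA = lfc_GPA,
         direction_A = dplyr::case_when(lfc_A > 0 ~ "up", lfc_A < 0 ~ "down",
                                        TRUE ~ "none"),
         direction_GPA = dplyr::case_when(lfc_GPA > 0 ~ "up", lfc_GPA < 0 ~ "down",
                                          TRUE ~ "none"))
}

#' Generate the synthetic count matrix
#'
#' Counts are negative-binomial with mean `baseline * 2^lfc(class, condition)`
#' and the specified dispersion (`var = mu + alpha mu^2`); replicates are
#' exchangeable and the draw is deterministic under the spec seed.
#'
#' @param spec A [gpa_scenario_spec()].
#' @param annotation Annotation from [gen_genome()] (class labels required).
#' @return List with `counts` (tibble, `gene_id` + samples), `sample_info`
#'   (`sample`, `condition`), and `truth` (per-gene planted cluster,
#'   fold changes and directions).
#' @export
gen_counts <- function(spec, annotation) {
  spec <- validate_scenario_spec(spec)
  if (spec$dispersion <= 0) abort("config error: dispersion must be positive")
  set.seed(child_seed(spec$seed, "counts"))
  genes <- annotation$genes
  if (!"class" %in% names(genes)) abort("annotation lacks gene class labels")
  eff <- gene_effects(spec, genes)
  baseline <- stats::rlnorm(nrow(genes), spec$baseline_meanlog, spec$baseline_sdlog)

  lfc_of <- list(none = rep(0, nrow(genes)), A = eff$lfc_A, GPA = eff$lfc_GPA)
  counts <- tibble(gene_id = genes$gene_id)
  info <- list()
  for (cond in GPA_CONDITIONS) {
    mu <- baseline * 2^lfc_of[[cond]]
    for (r in seq_len(spec$n_replicates)) {
      smp <- sprintf("%s_r%d", cond, r)
      counts[[smp]] <- rnbinom(nrow(genes), mu = mu, size = 1 / spec$dispersion)
      info[[length(info) + 1L]] <- tibble(sample = smp, condition = cond)
    }
  }
  list(counts = counts, sample_info = bind_rows(info),
       truth = mutate(eff, baseline_mean = baseline))
}

#' Simulate a complete GPA scenario
#'
#' Runs [gen_genome()], [gen_peaks()] and [gen_counts()] and bundles the
#' results with their ground truth.
#'
#' @param spec A [gpa_scenario_spec()].
#' @return A `gpa_scenario` list: `spec`, `genome`, `annotation`, `peaks`,
#'   `counts`, `sample_info`, `truth` (list of `peaks` and `genes` tibbles).
#' @export
simulate_gpa_scenario <- function(spec = gpa_scenario_spec()) {
  g <- gen_genome(spec)
  p <- gen_peaks(spec, g$genome, g$annotation)
  cts <- gen_counts(spec, g$annotation)
  structure(
    list(spec = spec, genome = p$genome, annotation = g$annotation,
         peaks = p$peaks, counts = cts$counts, sample_info = cts$sample_info,
         truth = list(peaks = p$truth, genes = cts$truth)),
    class = "gpa_scenario"
  )
}

#' @export
print.gpa_scenario <- function(x, ...) {
  cat(sprintf("<gpa_scenario> %d genes, %d peaks (%s), %d samples\n",
              nrow(x$annotation$genes), nrow(x$peaks),
              paste(unique(paste0(x$peaks$tf, "@", x$peaks$condition)), collapse = ", "),
              nrow(x$sample_info)))
  invisible(x)
}

#' Write a scenario to disk in standard formats
#'
#' Emits `genome.fa` (60-column FASTA), `genes.gtf`, one
#' `{tf}_{condition}.narrowPeak` per peak set, `counts.tsv`,
#' `truth_peaks.tsv`/`truth_genes.tsv`, `motifs.txt` and `scenario.yaml`.
#'
#' @param scenario A `gpa_scenario`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "gpa_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(scenario$genome, file.path(dir, "genome.fa"))
  write_gene_models(scenario$annotation, file.path(dir, "genes.gtf"))
  sets <- split(scenario$peaks, paste(scenario$peaks$tf, scenario$peaks$condition, sep = "_"))
  for (nm in names(sets)) {
    write_narrowpeak(sets[[nm]], file.path(dir, paste0(nm, ".narrowPeak")))
  }
  write_counts(scenario$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(scenario$truth$peaks, file.path(dir, "truth_peaks.tsv"), progress = FALSE)
  readr::write_tsv(scenario$truth$genes, file.path(dir, "truth_genes.tsv"), progress = FALSE)
  write_motifs(scenario$spec$motifs, file.path(dir, "motifs.txt"))
  sp <- scenario$spec
  yaml::write_yaml(
    list(n_chroms = sp$n_chroms, chrom_length = sp$chrom_length,
         n_genes = sp$n_genes, gene_classes = as.list(sp$gene_classes),
         motif_set = as.list(sp$motif_set), cobind_fraction = sp$cobind_fraction,
         peak_jitter_sd = sp$peak_jitter_sd, peak_halfwidth = sp$peak_halfwidth,
         n_replicates = sp$n_replicates, fold_changes = as.list(sp$fold_changes),
         dispersion = sp$dispersion, seed = sp$seed),
    file.path(dir, "scenario.yaml")
  )
  invisible(dir)
}
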