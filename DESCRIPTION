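Package: peakcross
Title: Integrating Transcription-Factor ChIP-Seq Peak Sets with RNA-Seq
    Expression Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking how combinations of transcription factors
    redirect each other's genomic binding and how binding relates to the
    direction of transcriptional regulation. Implements summit-centred
    window overlap classification of ChIP-seq peak sets (unique/common and
    generalized multi-set Venn partitions), nearest-TSS and genomic-feature
    annotation of peaks, known-motif scanning around peak summits with
    positional and per-peak occurrence summaries, a self-contained
    negative-binomial Wald differential-expression stage with
    median-of-ratios normalization, PAM (k-medoids) clustering of
    condition-mean expression profiles, motif-stratified
    direction-of-regulation analysis, and a weighted Kolmogorov-Smirnov
    gene-set enrichment statistic with gene-set permutation. A synthetic
    scenario generator emulates a default factor, a recruiter that
    redirects it to a new gene class, and a co-binder without its own motif
    at shared sites, with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    mclust,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2,
    cluster,
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
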