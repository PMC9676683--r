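---
title: "Methods: summit-window peak algebra and expression integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summit-window peak algebra and expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakcross)
```

This vignette is the package's own account of its models and procedures:
what each stage assumes, which tunables matter, what the synthetic
benchmark does and does not emulate, and where genuinely open design
choices were settled.

## The scientific setting

The package targets a recurring pattern in developmental gene regulation:
a *default* transcription factor (call it A) binds one repertoire of
targets on its own; a *recruiter* (P) opens or marks a second repertoire so
that A binds there too; and a *co-binder* (G) associates with A's sites
without its own DNA motif being present, while separately acting as a
DNA-binding repressor at its own-motif sites. Evidence for such a model
comes from intersecting per-condition ChIP-seq peak sets, from motif
content of the intersection classes, and from the direction of expression
change of the genes assigned to each peak class. All inputs are
post-primary-analysis artifacts: called peaks with summits, gene models,
gene-level counts, and motif models.

## Summit-window overlap

Peaks vary widely in width, so all overlap logic uses a fixed-width window
centred on the summit: \[s − w/2, s + w/2), default `w = 300` bp, half-open
coordinates, clipped at chromosome bounds. Two windows overlap iff their
intersection is at least 1 bp; under half-open arithmetic summits exactly
299 bp apart overlap and 300 bp apart do not. We treat that boundary as
exact and test it as such.

For more than two sets, windows are pooled and merged by *single linkage*:
any chain of pairwise-overlapping windows collapses into one merged region,
even when the chain's ends do not overlap each other. This mirrors
merge-based peak tooling and has a documented consequence: class counts
depend on merging, so `partition_counts()` reports both merged-region
counts and contributing-source-peak counts. The two differ exactly when
several peaks of one set fall into one region — which is also why published
unique/common group sizes from merge-based pipelines need not sum to the
per-set totals.

## Nearest-TSS assignment and genomic features

Each peak is assigned to the gene minimizing |summit − TSS| on its
chromosome, with exact-distance ties broken toward the lexicographically
smaller gene id (a stated, testable rule rather than an arbitrary one).
Signed distance is measured in the gene's orientation, negative upstream.
Feature classes are evaluated at the summit with fixed priority
promoter > exon > intron > downstream > intergenic; the promoter is
TSS ± 3 kb by default. The promoter half-width is a convention, not a
derived quantity — annotation tools differ and the upstream literature
rarely states theirs — so it is an explicit argument
(`genomic_features(promoter_window = )`). Association of peak groups with
expression clusters counts a peak for cluster c iff its summit lies within
±5 kb (inclusive) of the TSS of ≥ 1 gene labelled c; a peak near genes of
two clusters counts once per cluster and is flagged, and fractions are over
the group's total size so they sum to ≤ 1.

## Motif scanning

Scanning covers ±125 bp around each summit (a 250 bp window), both strands.
Consensus motifs use the IUPAC degenerate alphabet with exact matching by
default; PWMs are scored as log2-odds against a uniform background with an
absolute threshold (default 80% of the maximal attainable score when the
motif file gives none). A palindromic motif matches both strands at the
same position; these duplicates collapse to one hit by default
(`dedup = TRUE`), and per-strand counting is available by switching it off.
Hit offsets are the *leftmost base* of the match relative to the summit,
which keeps |offset| ≤ halfwidth and makes positional curves
strand-agnostic. The uniform background is a deliberate simplification:
the package ships no genomic background model, and its thresholds are not
calibrated p-values.

The default motif set (`gpa_default_motifs()`) contains synthetic
stand-ins — an E-box with 5' A preference (`ACAGCTG`, AtEAM-like), an
AT-rich POU-homeodomain-type consensus, and an AATC-core Gfi1-type
consensus. They are deliberately editable inputs: real analyses should
supply the lab's own matrices.

## The differential-expression stage

The DE stage is intentionally minimal and fully specified, so that its
statistical behaviour is testable in isolation:

* **Normalization** — median-of-ratios size factors over genes positive in
  every sample, rescaled to geometric mean 1. This assumes most genes are
  not differentially expressed; the synthetic benchmark respects that
  assumption (below).
* **Dispersion** — per-gene method of moments,
  α̂_c = (s²_c − μ̄_c)/μ̄_c² within each condition, averaged, clamped to
  \[1e−8, ∞). No information is shared across genes; this is the main
  difference from shrinkage-based DE packages, and it costs power at very
  small n.
* **Test** — Wald statistic log2((μ̂₁+0.5)/(μ̂₂+0.5)) / SE with the NB
  delta-method SE, referred to a **t distribution with n₁+n₂−2 df**.
  The t reference is the package's choice where a plain normal reference
  would be anti-conservative: with 3 vs 3 replicates the variance estimate
  has ~4 df, and a simulation at the package's calibration conditions
  (10,000 null genes, dispersion 0.1) gives empirical type-I ≈ 0.12 under
  the normal reference versus ≈ 0.045 under the t. The acceptance suite
  re-runs this calibration.
* **Selection** — FDR ≤ 0.05 and |log2FC| ≥ 1.5, inclusive. Upstream
  descriptions of this threshold pair vary between strict and inclusive
  phrasing; we adopt inclusive and expose `strict = TRUE`.

Two degenerate-input rules are worth stating: genes with all-zero counts in
both conditions get p = 1, log2FC = 0 and a flag; and "identical counts in
every sample implies log2FC = 0" holds exactly when size factors are equal,
because normalization by unequal factors legitimately moves constant genes.

With 2 replicates per condition the t reference has 2 df and the test has
essentially no power for realistic effects; that is a property of any
per-gene-variance test, not a bug. The synthetic scenario therefore
defaults to 3 replicates per condition (chosen by this power analysis, not
fitted to any outcome), while the functions accept any n ≥ 2.

## PAM clustering of expression profiles

Clustering operates on the genes × conditions matrix of mean normalized
counts for DE genes, z-scored per gene so that clusters reflect *patterns*
rather than magnitudes. The partitioner is PAM with a deterministic greedy
BUILD (ties to the lowest row index) and a SWAP phase that repeatedly
applies the single best strictly-improving exchange — the objective is
non-increasing by construction, which the tests assert, and the result is
reproducible without any seed. A second-level PAM with k = 2 can split one
primary cluster into lettered subclusters (the C-1 → C-1A/C-1B pattern);
the pipeline splits the *largest* primary cluster by default, which in the
synthetic scenario is the merged up-in-both/up-mainly-in-A pair. k itself
is a user choice (pipeline default k = 4 primary + one split, i.e. five
labels); no internal criterion such as silhouette is applied, matching how
such cluster counts are typically fixed a priori in the upstream
literature.

## Direction-of-regulation analysis

Peak classes from the motif partition are crossed with DE directions: each
peak votes once through its nearest-TSS gene (up / down / non-DE), and
both a peak-level and a gene-level table are emitted — they differ when a
gene carries several peaks, and which one to read depends on whether the
question is about binding events or genes. Smoothed density curves of
signed TSS distance per (class × direction) use a Gaussian kernel,
bandwidth 2 kb, evaluated on a 200-point grid over ±30 kb and scaled to
counts, so a curve integrates (to ~1%) to its class count. Kernel and
bandwidth are presentation choices the upstream literature leaves unstated;
both are arguments.

## GSEA

The enrichment score is the weighted KS running-sum statistic; with
p = 0 it reduces to the classic KS statistic (cross-checked against an
independent implementation in the tests, and against `fgsea` for p = 1).
Because designs with two or three replicates per phenotype cannot support
phenotype permutation, significance uses **gene-set permutation**: null
scores from random same-size sets, NES = ES / mean(|null ES| of the same
sign), and the standard sign-stratified pooled FDR q. The ranking metric is
signal-to-noise by default, with the conventional 0.2·|mean| floor applied
only when the pooled SD is exactly zero, and a plain log2 ratio of means as
the small-n fallback.

## The synthetic scenario: what it emulates, and what not

`gpa_scenario_spec()` defaults define the benchmark conditions:

* 2 chromosomes × 1 Mb, 200 genes on non-overlapping ~5–10 kb slots
  (uniform background sequence, 50/50 strand, two terminal exons).
* Five gene classes: `neuronal_common` (25; up in both induced
  conditions, the C-1A analogue), `neuronal_only` (20; up in A, 0.4× the
  effect in GPA — C-1B), `hc_only` (25; up only in GPA — C-2),
  `downregulated` (20; half down in A, half down in GPA — C-3/C-4), and a
  `background` majority (110). The background majority is required for the
  median-of-ratios assumption to hold; the effect size defaults to
  |log2FC| = 3 with NB dispersion 0.05 and baseline means log-normal
  around 100.
* Binding: one peak per (TF, condition, target gene), summit ~500 bp
  upstream of the TSS with N(0, 20 bp) jitter; motif instances written into
  the sequence within ±40 bp of the intended summit (in place, so
  coordinates stay stable); the co-binder G copies `cobind_fraction = 0.5`
  of A's GPA summits motif-free and places own-motif promoter peaks at the
  genes repressed in GPA. G's own-motif peaks deliberately exclude the
  down-in-A-only half of the repressed class: a repressor expressed only in
  the GPA condition cannot be the cause of repression where it is absent,
  and the direction analysis runs on the GPA contrast.
* Counts: NB with mean = baseline × 2^lfc, 3 replicates per condition
  (power analysis above), exchangeable replicates, all draws deterministic
  under the spec seed.

What it does *not* emulate: read-level noise and peak-caller artifacts
(peaks are emitted directly, not called), chromatin accessibility, GC or
repeat structure in the background sequence, correlated replicates, batch
effects, and motif instances in background regions beyond what uniform
sequence produces by chance. Passing the recovery tests therefore shows the
*integration logic* is correct under the stated statistical structure — it
does not certify performance on any particular real dataset.

## Numerical and degenerate-input conventions

* All coordinates are 0-based half-open internally; GTF converts at the
  boundary (1-based closed → half-open), and narrowPeak summit offset −1
  falls back to the interval midpoint (floor).
* Chromosome names are taken verbatim; a mismatch across input files is a
  hard error naming the files, never silently harmonized.
* `summit_windows(w = 1)` gives \[s, s+1); windows clip at 0 without
  needing chromosome lengths, and at the right end only when lengths are
  supplied (missing lengths there are an error, not a guess).
* PAM ties break to the lowest index at every decision point; the swap
  acceptance threshold is a strict improvement by > 1e−12 to avoid cycling
  on exact ties.
* The positional-distribution bin grid anchors at −halfwidth; `binsize`
  must divide 2·halfwidth exactly or the call errors.
* Peaks whose scan window is clipped by a sequence end are scanned on the
  clipped window and flagged in the hit table.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data at desk scale: 2 Mb of genome, 200 genes, ~150 peaks, 10,000-gene
null calibrations, 100–200 replicate power simulations, and 500–1000
gene-set permutations. These sizes were chosen so the full validation
suite completes in minutes on a single CPU while keeping every Monte Carlo
band (type-I in \[0.03, 0.07\], power ≥ 0.95, ARI ≥ 0.9) well away from
its sampling noise.
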