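# peakcross

Integrating transcription-factor ChIP-seq peak sets with RNA-seq expression
clusters, for studies of **combinatorial TF control of cell identity** — the
situation where one factor binds a set of targets on its own, a second factor
recruits it to a new target repertoire, and a third factor rides along at
shared sites while acting independently (as repressor) at its own sites. The
motivating system is the hair-cell regulatory trio Gfi1/Pou4f3/Atoh1 (GPA),
but every function is generic over peak sets, gene models, count matrices and
motif models.

The package is aimed at computational biologists who have already called
peaks (ENCODE narrowPeak) and summarised RNA-seq to gene-level counts, and
now want the *integration* layer as tested, scriptable functions rather than
a chain of one-off tools.

## What it computes

**Peak-set algebra on summit windows.** Each peak is reduced to the window
\[s − w/2, s + w/2) around its summit s (default w = 300 bp, half-open
coordinates). Two peaks overlap iff their windows share ≥ 1 bp. For two sets
this yields the unique/common/unique classification; for k sets, windows are
pooled and merged transitively (single linkage) and each merged region is
labelled with its contributing set names — the generalized Venn classes
(`classify_pair()`, `membership_partition()`).

**Peak-to-gene annotation.** Nearest-TSS assignment with gene-oriented
signed distance (negative = upstream) and deterministic tie-breaks; ±5 kb
TSS-window association of peak groups with expression clusters; and
genomic-feature classes with priority promoter > exon > intron > downstream >
intergenic (`nearest_tss()`, `cluster_association()`, `genomic_features()`).

**Known-motif scanning.** IUPAC consensus (exact degenerate match) or PWM
(log2-odds vs uniform background) scanning of both strands in the ±125 bp
around each summit, per-peak occurrence histograms, positional frequency
curves, and the motif-content partition {own-motif-only, E-box-containing,
neither} (`scan_window()`, `motif_histogram()`, `positional_distribution()`,
`partition_by_motif()`).

**Differential expression.** A self-contained negative-binomial Wald stage:
median-of-ratios size factors

&nbsp;&nbsp;&nbsp;&nbsp;sf_j = median_g ( k_gj / (∏_j k_gj)^(1/m) ),

per-gene method-of-moments dispersion α̂ = max{(s² − μ̄)/μ̄², 0} averaged
across the two conditions, Wald statistic log2FC / SE with the delta-method
SE and a t reference with n₁+n₂−2 df, BH adjustment, and selection at
FDR ≤ 0.05 and |log2FC| ≥ 1.5 (`nb_wald_test()`, `select_de()`).

**Expression clustering.** Deterministic PAM (k-medoids, BUILD + best-swap
SWAP) on z-scored condition-mean profiles, with an optional second-level
split of one cluster into lettered subclusters (`cluster_de()`,
`pam_kmedoids()`).

**Direction of regulation.** Motif-stratified peak classes are voted by
their assigned genes' DE direction, and Gaussian-smoothed peak-density
curves over signed TSS distance (±30 kb, 2 kb bandwidth) separate
near-promoter repression from distance-independent activation
(`direction_fractions()`, `distance_direction_curve()`).

**GSEA.** The weighted Kolmogorov–Smirnov running-sum enrichment score
(hit increment |r|^p / Σ_set |r|^p, miss decrement 1/(N − N_set)), normalized
against a gene-set-permutation null: NES = ES / mean |null ES of same sign|,
with sign-stratified FDR q (`rank_genes()`, `enrichment_score()`,
`nes_fdr()`).

**Synthetic scenario generator.** `simulate_gpa_scenario()` builds a
self-contained benchmark — genome FASTA, gene models, per-TF/condition
narrowPeak files, NB count matrix — with a default TF "A" bound at neuronal
gene classes, a recruiter "P" that redirects A to a hair-cell-like class
(planting both motifs at the new elements), and a co-binder "G" that copies
half of A's summits motif-free while repressing its own-motif promoter
targets. Every peak and gene carries a ground-truth label, so the whole
pipeline can be validated by `scenario_recovery()`.

## Worked example

```r
library(peakcross)

sc <- simulate_gpa_scenario(gpa_scenario_spec(seed = 1))
sc
#> <gpa_scenario> 200 genes, 155 peaks (A@A, A@GPA, P@GPA, G@GPA), 9 samples

report <- run_gpa_pipeline(sc, pipeline_params(seed = 1))

report$algebra$pair_counts          # A peaks: alone vs full combination
#>   membership     n
#> 1 A_unique      20
#> 2 common        50
#> 3 GPA_unique    25

partition_counts(report$algebra$partition_gpa)   # 3-way Venn classes
#>   members n_regions n_peaks
#> 1 A              13      13
#> 2 A+G+P          13      39
#> 3 A+G            12      24
#> 4 A+P            12      24
#> 5 G              10      10

dplyr::filter(report$direction$fractions, level == "peak")
#>   level motif_class     direction     n fraction
#> 1 peak  ebox_containing down          0        0
#> 2 peak  ebox_containing non-DE        0        0
#> 3 peak  ebox_containing up           25        1
#> 4 peak  own_only        down         10        1
#> 5 peak  own_only        non-DE        0        0
#> 6 peak  own_only        up            0        0

scenario_recovery(report, sc$truth)
#>   metric                value     n
#> 1 recruited_unique_frac 1        25
#> 2 retained_common_frac  1        25
#> 3 cobound_common_frac   1        25
#> 4 own_motif_down_frac   1        10
#> 5 ebox_up_frac          1        25
#> 6 cluster_ari           0.974    90
```

Reading the numbers: the 25 A peaks that exist only in the full GPA
condition are exactly the recruiter-dependent sites (`recruited_unique_frac
= 1`); every co-binder peak placed on an A summit lands in a merged region
containing A (`cobound_common_frac = 1`); G peaks carrying only the G motif
sit at repressed genes (down fraction 1) while E-box-containing G peaks sit
at activated genes (up fraction 1); and PAM on the DE genes' condition-mean
profiles recovers the planted five-cluster structure at adjusted Rand index
0.97. `report$gsea$results` adds NES and FDR q per recovered cluster against
the induced-vs-uninduced ranking, and `autoplot()` / `plot_*()` functions
render the volcano, cluster-profile, positional-motif and direction-curve
figures.

On real data: read inputs with `read_narrowpeak()`, `read_gene_models()`,
`read_counts()`, `read_motifs()` (or `read_scenario()` for a directory laid
out like `write_scenario()` output) and call the same functions.

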