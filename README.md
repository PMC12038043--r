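# flcpipe

Cross-modal analysis of fetal Leydig cell differentiation in the embryonic
testis: an R pipeline for the computations that join a single-nucleus
multiome (snRNA-seq + snATAC-seq), transcription-factor ChIP-seq, and bulk
knockout RNA-seq into one picture of how *Nr2f2*-positive interstitial
progenitors become steroidogenic Leydig cells.

It is written for computational biologists who have the standard upstream
outputs in hand (count matrices, called peak BEDs, a bulk DE table) and
need the bespoke downstream statistics, each as a small deterministic
function:

- **QC gating** — joint per-cell RNA + ATAC filters with strict thresholds
  (mito < 10%, ribo < 10%, hemoglobin < 0.5%, genes > 500; FRiP > 20%,
  250 < fragments < 25,000, blacklist < 5%).
- **Cluster chromatin similarity** — Euclidean distances between cluster
  mean profiles over the 2000 most variable ATAC peaks,
  d(a,b) = sqrt(Σ_p (m̄_a[p] − m̄_b[p])²), with a dendrogram and
  nearest-cluster queries.
- **Differential testing** — Wilcoxon rank-sum for expression; for
  accessibility a logistic-regression likelihood-ratio test,
  `group ~ peak + fragment_total` vs `group ~ fragment_total`
  (χ², 1 d.f.), so depth-confounded peaks are not called. BH-adjusted
  p < 0.05 throughout.
- **ChIP peak annotation** — 300 bp midpoint resizing, blacklist and
  canonical-chromosome filters, and exclusive genomic-context classes by
  signed distance d to the nearest TSS: promoter d ∈ [−1 kb, 0],
  gene body, upstream d ∈ [−10 kb, −1 kb), intergenic.
- **Integration** — nearest-gene target assignment, target×DEG Venn
  counts, DA-peak × ChIP overlap fractions (≥ 1 bp; percentages truncated,
  not rounded, to one decimal), and peak–gene links by Pearson correlation
  of accessibility vs expression within ±500 kb of the TSS.
- **Motif ranking** — JASPAR PFM log-odds scanning (hit = window ≥ 80% of
  max score, either strand), one-sided hypergeometric enrichment of
  DA peaks vs a GC-matched background, and combined TF ranking by the
  rank-sum of motif and differential-expression adjusted p-values,
  including the run restricted to ChIP-bound DA peaks.
- **Empirical projection** — bulk DEG lists projected onto single-nucleus
  clusters via z-scored per-cluster average expression; a cluster is
  "affected" when more than 20% of the DEGs exceed z = 1; gene groups from
  the largest dendrogram cut whose smallest group keeps ≥ 2% of the genes.
- **Synthetic data** — a generator producing a self-consistent desk-scale
  testis multiome (matrices, QC table, peak/gene geography, ChIP peaks
  with exact context composition and designed DA coverage, peak sequences
  with planted motifs, a bulk DE table) plus ground-truth tables for every
  recovery test.

## Worked example

Run the whole pipeline on the bundled synthetic study design:

```r
library(flcpipe)
out <- file.path(tempdir(), "demo")
run_cli(c("all", "--seed", "7", "--outdir", out))

read.delim(file.path(out, "nearest_cluster.tsv"))
#>   target nearest distance
#> 1     c3      c0 4.366807

read.delim(file.path(out, "chip_da_overlap.tsv"))
#>   group n_da_peaks n_overlapping percent
#> 1    c0         49            18    36.7
#> 2    c3         84             4     4.7

head(read.delim(file.path(out, "tf_candidates_c0.tsv")), 3)
#>   tf_gene_id motif_id     de_adj_p  motif_adj_p combined_rank
#> 1   gene_003 motif_03 3.167233e-18 5.412924e-07             1
#> 2   gene_002 motif_02 2.640568e-13 5.412924e-07             2
#> 3   gene_001 motif_01 9.705484e-06 5.412924e-07             3

read.delim(file.path(out, "projection_affected_down.tsv"))
#>   cluster fraction affected
#> 1      c0      0.5     TRUE
#> 2      c1      0.5     TRUE
#> 3      c2      0.0    FALSE
#> ...
```

Reading the output: the chromatin profile of the fetal-Leydig-like cluster
`c3` is closest to the progenitor-like cluster `c0` (the designed
relationship); 36.7% of the DA peaks detected on the `c0` side carry a
ChIP peak versus 4.7% on the `c3` side (the generator planted coverage of
45% / 5% of the *true* DA peaks — detected sets dilute that with weaker
true positives); the three TFs whose motifs were planted in `c0`-side
peaks are recovered and ranked by the combination of motif enrichment and
differential expression; and the clusters whose marker genes seeded the
bulk "downregulated" list are the ones called affected.

Every stage can also be run on its own (`simulate`, `qc`, `similarity`,
`diff`, `annotate`, `integrate`, `motifs`, `project`) against the same
output directory, from R via `run_cli()` or from a shell via the wrapper
in `inst/scripts/flcpipe`. Re-running any stage with the same seed and
configuration reproduces its outputs byte for byte.

## Layout

```
R/                  implementation (one file per analysis module)
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R
vignettes/flcpipe-methods.Rmd   the methods vignette (models, parameters,
                                design choices, limitations)
```
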