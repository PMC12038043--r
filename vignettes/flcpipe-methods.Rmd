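---
title: "Methods: cross-modal analysis of fetal Leydig cell differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-modal analysis of fetal Leydig cell differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flcpipe)
options(flcpipe.verbose = FALSE)
```

## The biological problem

Fetal Leydig cells, the androgen-producing cells of the embryonic testis,
differentiate from a pool of non-steroidogenic interstitial progenitors
marked by the orphan nuclear receptor *Nr2f2* (COUP-TFII). Resolving that
transition requires combining several assays measured on different material:
a single-nucleus multiome (snRNA-seq + snATAC-seq of the same nuclei), ChIP-seq
of the candidate regulator in whole tissue, and bulk RNA-seq of knockout
versus control gonads. None of the individual assays is novel; the analysis
lives in the *joints* between them — which cluster's chromatin most resembles
the Leydig cluster, which differentially accessible (DA) peaks carry a
binding peak of the regulator, which accessible peaks correlate with which
genes, and which single-nucleus populations carry the transcriptional
signature of the knockout. `flcpipe` implements exactly those joints as
testable, deterministic functions, and ships a synthetic-data module that
generates a self-consistent desk-scale "testis multiome" with recorded
ground truth so every downstream computation can be scored.

## Per-cell quality gates

Cells are gated jointly on both assays with strict inequalities: RNA
requires `< 10%` mitochondrial, `< 10%` ribosomal, `< 0.5%` hemoglobin
content and `> 500` detected genes; ATAC requires `> 20%` fraction of reads
in peaks, `> 250` and `< 25,000` fragments in peaks, and `< 5%` of fragments
in blacklist regions. The wording of the criteria is strict, so boundary
cells (exactly 10% mitochondrial content, exactly 250 fragments) fail. The
hemoglobin criterion is interpreted as a fraction of counts (the field's
usual convention); it is not stated anywhere whether it is a fraction of
counts or of detected genes, so the choice is documented here rather than
hidden. Doublet and ambient-RNA removal are upstream tools' jobs and are not
re-implemented; the generator can emulate their effect by planting an
explicit fail set.

## Cluster chromatin similarity

The per-cell ATAC signal is depth-normalized (counts divided by the cell's
fragment total, rescaled by the median total — a monotone, transparent
transform), the `n_variable_peaks = 2000` most variable peaks are selected
by plain across-cell variance, per-cluster mean profiles are averaged, and
pairwise Euclidean distances between cluster profiles feed a
complete-linkage dendrogram and nearest-cluster queries. Two deliberately
simple choices are made where the referenced toolchain's behavior is more
elaborate: variance replaces a fitted dispersion model for peak selection,
and complete linkage (the base `hclust` default) is used but configurable
(`complete|average|single`). Both choices are safe because the downstream
use is a *ranking* of cluster distances, which is robust to the selector,
and both are fully oracle-testable. Clusters below `min_cluster_cells = 3`
are excluded, mirroring the exclusion of a 2-cell cluster in the motivating
study design.

## Differential expression and accessibility

Expression contrasts use a two-sided Wilcoxon rank-sum test per gene on
log-normalized counts (counts scaled to 10,000 per cell, then `log1p`),
with Benjamini–Hochberg correction per contrast and significance at
`adj_p < 0.05` strict. No minimum-fraction or fold-change prefilter is
applied by default, because the stated analysis thresholds only the
adjusted p-value. The effect is the log2 ratio of mean normalized
expression with pseudocount 1.

Accessibility contrasts are the statistically interesting case: sequencing
depth differs per cell and inflates apparent accessibility, so the test is
a logistic-regression likelihood-ratio test with the per-cell fragment
total as covariate — cluster membership is modeled as
`group ~ peak_signal + fragment_total` and compared to the covariate-only
model with a 1-d.f. chi-square. A peak whose openness is driven purely by
depth is therefore not called, while an uncorrected proportion test is
misled; the acceptance suite demonstrates both directions on planted
designs. The effect size is `log2((rate_a + eps)/(rate_b + eps))` with
`eps = 1/(n_a + n_b)` so all-closed groups stay finite. Peaks closed in
every cell of both groups are skipped with a log message.

## ChIP peak post-processing and genomic context

Called ChIP peaks are resized to 300 bp centered on their midpoints
(`[mid - 150, mid + 150)` with `mid = floor((start + end)/2)`, clipped at
chromosome bounds), filtered against blacklist intervals (any 1-bp overlap
excludes; abutting intervals, under the package's uniform 0-based half-open
convention, do not overlap) and against non-canonical chromosomes
(chr1-19, X, Y by default). Each surviving peak is classified by its
midpoint against the nearest TSS, with the signed distance taken in gene
orientation and exclusive classes in precedence order:

* **promoter** — signed distance in `[-1000, 0]` (a midpoint exactly at the
  TSS is a promoter peak);
* **gene body** — midpoint inside the nearest gene's body `[start, end)`;
* **upstream** — signed distance in `[-10000, -1000)`;
* **intergenic** — everything else, including peaks on gene-less
  chromosomes.

The upstream window is implemented as `[-10 kb, -1 kb)`. A published
description of the same class prints "(−10 kb to 1 kb)", which is
inconsistent with its own promoter definition; the package follows the
internally consistent reading and flags the discrepancy here rather than
silently reconciling it elsewhere. Equidistant-TSS ties break by
lexicographic gene id and are logged. Classification is keyed to the peak
midpoint rather than any-overlap because the peaks are already
midpoint-centered 300-mers, making the rule tie-free.

## Integration statistics

ChIP target genes are the union of nearest genes over significant peaks,
with a promoter-restricted variant. Overlap statistics count a DA peak as
"containing" a ChIP peak when the intervals share at least 1 bp. Reported
percentages are **truncated** to one decimal, not rounded: printed pairs
such as 328/684 → 47.9% are consistent with truncation but not with
round-half-up, so `percent_trunc()` floors.

Peak–gene links are Pearson correlations, across cells, of normalized
accessibility (binarized signal over a per-cell depth factor) against
log-normalized expression, for every peak–gene pair whose midpoint lies
within ±500 kb of the TSS (the conventional search window, configurable).
Significance uses the analytic t-transform of r with n−2 d.f. and BH
correction over all tested pairs at `adj_p < 0.05`. A GC-matched background
z-score variant exists in some toolchains; the analytic form was chosen
because it is deterministic and exactly checkable against the reference
correlation test, which the unit suite does. Zero-variance peaks or genes
are skipped with a log message. The linkage significance cutoff and window
are not externally specified anywhere, so both are explicit, documented
parameters.

## Motif scanning, enrichment and TF ranking

JASPAR-format PFMs (bracketed or plain) are converted to log-odds against
the uniform background with a pseudocount. A scan hit is any window, on
either strand, scoring at least `threshold_frac = 0.8` of the motif's
maximum attainable log-odds — a simple deterministic rule; p-value
calibrated thresholds are out of scope. Enrichment of a motif in foreground
(DA) peaks versus background peaks is the one-sided hypergeometric upper
tail on the 2×2 table, BH-corrected over motifs; the acceptance suite
checks it against direct `choose()` enumeration over every table with
margins up to 30 and against a 10,000-draw permutation null. Backgrounds
are GC-matched by sampling non-foreground peaks to the foreground's GC
histogram in bins of 0.05, falling back to the whole pool when a bin is
short (logged). For the unrestricted run the background pool is all tested
peaks outside the foreground; the stated analysis does not define it, so
the default is documented here.

Candidate TFs must pass both `motif adj_p < 0.05` and
`DE adj_p < 0.05` upregulated on the relevant side. The "combination" of
the two criteria is operationalized as a rank-sum — each TF is ranked by
ascending motif adjusted p and by ascending DE adjusted p, and ordered by
the sum (ties by motif adjusted p, then gene id). Rank-sum is scale-free:
any monotone transform of either p-value column leaves the ordering
unchanged, which the suite asserts. A product of −log10 p would weight the
tails more aggressively; rank-sum was preferred exactly because no formula
is externally prescribed and order-only semantics are the weakest defensible
assumption. The restricted analysis re-runs the same machinery with the
foreground narrowed to DA peaks carrying a ChIP peak and the background set
to the remaining DA peaks of the same side, so it asks specifically "what
distinguishes the bound DA peaks from the unbound ones".

## Bulk-DEG empirical projection

For each direction (up/down) of a bulk knockout-vs-control DE table
(consumed, never fitted — bulk model fitting is out of scope), the
projection computes per-cluster mean log-normalized expression of the DEG
list, z-scores each gene across clusters (sample n−1 standard deviation;
constant rows become zeros and are flagged, not dropped), groups genes by a
complete-linkage dendrogram cut at the largest k whose smallest group holds
at least `ceiling(0.02 × n_genes)` genes (k = 1 when no k ≥ 2 qualifies,
and also when all rows are identical, where any cut would be arbitrary),
and calls a cluster **affected** when more than 20% of the genes exceed
z = 1 in it — both comparisons strict. The affected-population statistic is
evaluated on the cluster-average z matrix; a per-cell scaled export exists
only for heatmap purposes. The cell-cycle/mitochondrial regression some
toolchains apply to the cosmetic per-cell heatmap is not implemented, since
it requires external gene lists and does not enter the statistic.

## The synthetic study design

`sim_design()` defaults define the package's desk-scale study conditions,
chosen once and used by the tests, the pipeline, and the acceptance script:

* 6 clusters (`c0`–`c5`) of 120 cells; `c0` plays the steroidogenic
  progenitor, `c3` the fetal Leydig cell.
* 300 genes and 400 ATAC peaks on two synthetic 10 Mb chromosomes. Genes
  occupy one territory per ~66 kb window so promoter/upstream windows of
  different genes can never collide, which makes every planted ChIP context
  class unambiguous by construction; ATAC peaks are 500 bp, at least 1 kb
  apart, so a 300 bp ChIP peak centered in one can never touch another.
* RNA counts are negative binomial (dispersion 0.5) with 15 marker genes
  per cluster at 4-fold elevation; ATAC entries are Bernoulli with
  cluster-specific open probabilities, modulated smoothly by each cell's
  fragment depth (`1 - (1 - p)^depth_factor`), with the fragment total
  exported as the covariate the DA test conditions on.
* 40 peaks are planted more open in `c0` and 70 in `c3` (rates 0.65 vs
  0.25), mirroring the 386:684 imbalance of the motivating contrast at
  desk scale; on non-DA peaks the progenitor's open-probability vector is
  an ε = 0.05 perturbation of the Leydig one while other clusters draw
  independent profiles, so the progenitor–Leydig pair is mutually nearest
  in chromatin space by design.
* ChIP peaks are placed with the genomic-context mix (35/34/26/5)% made
  exact by largest-remainder apportionment, and cover 45% of `c0`-side and
  5% of `c3`-side planted DA peaks (mirroring the contrast between ~44%
  and ~4% coverage that motivates the integration), with ChIP-covered DA
  peaks planted with motifs first so the restricted ranking has something
  real to find.
* QC metrics are drawn from scaled Beta distributions strictly inside the
  passing ranges, and failures are planted by explicit override, so the
  failing set is exact rather than a tail event. Detected-gene totals are
  drawn, not derived from the 300-gene matrix, because they emulate
  full-transcriptome totals.
* The bulk DE table plants its up list in the markers of one unaffected
  cluster and its down list in the markers of the progenitor and one other
  cluster, with null p-values drawn from Uniform(0.05, 1) so that exactly
  the planted genes are BH-significant — a construction-oracle property
  that real DESeq2 tables do not share and which exists purely so recovery
  tests can be exact.

Every generator is a pure function of (design, seed): sub-streams are
derived deterministically from the master seed and the caller's RNG state
is restored, so `simulate --seed 7` is byte-identical across runs.

What the synthetic data does **not** emulate: fragment-level ATAC
structure, doublets and ambient contamination, realistic mean–variance
relationships across the transcriptome, linkage disequilibrium between
neighboring peaks, or genome-scale feature counts. Passing tests therefore
demonstrate the correctness of the computations under the designed
statistical structure, not the biological performance of the upstream
assays at genome scale.

## Numerical choices and degenerate inputs

* All coordinates are 0-based half-open everywhere inside the package;
  conversion to 1-based closed happens only inside the GenomicRanges bridge
  used for overlap arithmetic.
* Wilcoxon p-values use the normal approximation with tie correction
  (accessibility-scale data are tie-heavy); genes constant across both
  groups short-circuit to p = 1, effect = 0.
* The LRT statistic is clamped at 0 against floating-point deviance noise.
* Correlations are clamped to [−1, 1] before the t-transform.
* BH is applied per contrast over all tested features.
* Distance/linkage ties: nearest-cluster and ranking tie-breaks are
  deterministic (sorted id order) so outputs are hash-stable.
* `percent_trunc` adds 1e-9 before flooring to protect exact decimal
  boundaries from floating-point representation.

## Problem sizes

The test suite and acceptance script run the full pipeline at the design
sizes above (720 cells, 400 peaks, 300 genes), type-I simulations at 1000
features × 400 cells, planted-recovery at 100 replicates of 200 + 200
cells, and exhaustive hypergeometric enumeration at margins ≤ 30. These
sizes were chosen so each property is measured with enough resolution for
its stated tolerance (e.g. a 3-binomial-s.d. band around 5% at 1000
features is ±2.1 points) while keeping the whole suite interactive.

## Known limitations

* The Wilcoxon and LRT implementations are the conventional choices behind
  the named single-cell toolchain, not byte-compatible re-implementations
  of it; results on real data will differ in the tails.
* GC-matched background sampling falls back to the full pool when a GC bin
  is underpopulated, which weakens matching on very small peak sets.
* The restricted TF ranking's background (remaining same-side DA peaks) is
  one of several defensible choices; with full ChIP coverage the background
  is empty and the enrichment degenerates to p = 1, which is reported
  honestly rather than special-cased.
* Bulk DE tables are consumed as given; no shrinkage, filtering or
  independent re-fitting is applied.
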