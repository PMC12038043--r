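#' ChIP target genes
#'
#' A target gene is the gene most proximal to a significant ChIP peak; the
#' target set is the union of nearest genes over all annotated peaks.
#' The promoter-restricted variant keeps only TSS-proximal peaks, matching
#' the study's repeat analysis on promoter-bound targets.
#'
#' @param annotated output of [classify_context()].
#' @param promoter_only restrict to peaks classified as promoter.
#' @return list with `targets` (unique gene ids) and `mapping` (per-peak
#'   peak name -> gene id data.frame).
#' @export
assign_targets <- function(annotated, promoter_only = FALSE) {
  keep <- !is.na(annotated$nearest_gene)
  if (promoter_only) keep <- keep & annotated$context == "promoter"
  mapping <- data.frame(peak = annotated$name[keep],
                        gene_id = annotated$nearest_gene[keep],
                        stringsAsFactors = FALSE)
  list(targets = sort(unique(mapping$gene_id)), mapping = mapping)
}

#' Three-set Venn counts for targets vs two DEG sets
#'
#' Counts of the seven exclusive regions of the Venn diagram of the ChIP
#' target set against the DEG sets of the two contrasted clusters, plus the
#' fraction of each DEG set covered by a target.
#'
#' @param targets,deg_a,deg_b character vectors over a shared gene universe.
#' @return list with `regions` (named 7-vector) and `coverage` (fraction of
#'   each DEG set that carries a ChIP target).
#' @export
intersect_deg_targets <- function(targets, deg_a, deg_b) {
  targets <- unique(targets); deg_a <- unique(deg_a); deg_b <- unique(deg_b)
  universe <- unique(c(targets, deg_a, deg_b))
  tm <- universe %in% targets
  am <- universe %in% deg_a
  bm <- universe %in% deg_b
  regions <- c(
    targets_only = sum(tm & !am & !bm),
    deg_a_only = sum(!tm & am & !bm),
    deg_b_only = sum(!tm & !am & bm),
    targets_deg_a = sum(tm & am & !bm),
    targets_deg_b = sum(tm & !am & bm),
    deg_a_deg_b = sum(!tm & am & bm),
    all_three = sum(tm & am & bm)
  )
  coverage <- c(
    deg_a = if (length(deg_a)) sum(am & tm) / length(deg_a) else NA_real_,
    deg_b = if (length(deg_b)) sum(bm & tm) / length(deg_b) else NA_real_
  )
  list(regions = regions, coverage = coverage)
}

#' Fraction of DA peaks containing a ChIP peak
#'
#' A differentially accessible peak "contains" a ChIP binding peak when the
#' two intervals overlap by at least 1 bp. The percentage is truncated to
#' one decimal, the convention consistent with the study's printed pairs.
#'
#' @param da_peaks [interval_set()] of one side's significant DA peaks.
#' @param chip [interval_set()] of significant ChIP peaks.
#' @param label group label carried into the report.
#' @return one-row data.frame: `group, n_da_peaks, n_overlapping, percent`.
#' @export
overlap_fraction <- function(da_peaks, chip, label = "") {
  n <- nrow(da_peaks)
  n_ov <- if (n == 0) 0L else sum(overlaps_any(da_peaks, chip))
  data.frame(group = label, n_da_peaks = n, n_overlapping = n_ov,
             percent = if (n == 0) NA_real_ else percent_trunc(n_ov, n),
             stringsAsFactors = FALSE)
}

#' Peak-gene links by accessibility-expression correlation
#'
#' For every peak-gene pair whose peak midpoint lies within `window` bp of
#' the gene TSS, the Pearson correlation across cells of normalized
#' accessibility (binarized signal over a per-cell depth factor) against
#' log-normalized expression is computed; p-values come from the analytic
#' t-transform of r with n-2 d.f. and are BH-adjusted over all tested
#' pairs. A link is a pair with `adj_p < adj_p_max`. Zero-variance peaks or
#' genes are skipped (logged).
#'
#' @param atac peaks x cells matrix (0/1 or counts).
#' @param rna genes x cells count matrix (same cells, same order).
#' @param peaks [interval_set()] with names matching `rownames(atac)`.
#' @param genes [gene_models()] with ids matching `rownames(rna)`.
#' @param depth per-cell ATAC fragment totals.
#' @param window search window around the TSS in bp (default 500 kb).
#' @param adj_p_max link significance threshold.
#' @return data.frame `peak_id, gene_id, correlation, p, adj_p, linked`.
#' @export
link_peaks <- function(atac, rna, peaks, genes, depth = NULL,
                       window = 5e5, adj_p_max = 0.05) {
  stopifnot(ncol(atac) == ncol(rna))
  n <- ncol(atac)
  if (n < 3) stop("need at least 3 cells to correlate")
  acc <- as.matrix(atac > 0) + 0
  depth <- depth %||% Matrix::colSums(atac)
  if (any(depth <= 0)) stop("per-cell depth must be positive")
  acc <- sweep(acc, 2, depth / stats::median(depth), "/")
  expr <- as.matrix(lognormalize(rna))
  mid <- (peaks$start + peaks$end) %/% 2L
  names(mid) <- peaks$name
  ## candidate pairs: same chromosome, |midpoint - TSS| <= window
  pairs <- do.call(rbind, lapply(seq_len(nrow(genes)), function(j) {
    sel <- peaks$chrom == genes$chrom[j] &
      abs(mid[peaks$name] - genes$tss[j]) <= window
    if (!any(sel)) return(NULL)
    data.frame(peak_id = peaks$name[sel], gene_id = genes$gene_id[j],
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      correlation = numeric(0), p = numeric(0),
                      adj_p = numeric(0), linked = logical(0)))
  }
  pairs <- pairs[pairs$peak_id %in% rownames(acc) &
                   pairs$gene_id %in% rownames(expr), , drop = FALSE]
  pv <- row_vars(acc)[pairs$peak_id]
  gv <- row_vars(expr)[pairs$gene_id]
  degenerate <- pv == 0 | gv == 0
  if (any(degenerate)) {
    flc_log("link_peaks: skipped %d pair(s) with zero variance", sum(degenerate))
    pairs <- pairs[!degenerate, , drop = FALSE]
  }
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    stats::cor(acc[pairs$peak_id[i], ], expr[pairs$gene_id[i], ])
  }, numeric(1))
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  adj <- bh_adjust(p)
  data.frame(peak_id = pairs$peak_id, gene_id = pairs$gene_id,
             correlation = r, p = p, adj_p = adj,
             linked = adj < adj_p_max, stringsAsFactors = FALSE)
}

#' Fraction of DA peaks linked to a gene
#'
#' Percentage of one side's DA peaks that appear in at least one
#' significant peak-gene link, truncated to one decimal.
#'
#' @param da_peak_ids character vector of DA peak ids.
#' @param links output of [link_peaks()].
#' @param label group label for the report.
#' @return one-row data.frame like [overlap_fraction()].
#' @export
linked_fraction <- function(da_peak_ids, links, label = "") {
  n <- length(da_peak_ids)
  linked_ids <- unique(links$peak_id[links$linked])
  n_l <- sum(da_peak_ids %in% linked_ids)
  data.frame(group = label, n_da_peaks = n, n_overlapping = n_l,
             percent = if (n == 0) NA_real_ else percent_trunc(n_l, n),
             stringsAsFactors = FALSE)
}
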