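#' Per-cluster average expression of a gene list
#'
#' Mean log-normalized expression of each listed gene in each cluster,
#' excluding clusters below `min_cells` (the study ignored its 2-cell
#' cluster). Genes absent from the matrix are dropped with a logged count.
#'
#' @param rna genes x cells raw count matrix.
#' @param labels per-cell cluster labels.
#' @param gene_ids the DEG list to project.
#' @param min_cells minimum cluster size.
#' @return matrix, retained genes x retained clusters.
#' @export
cluster_means <- function(rna, labels, gene_ids, min_cells = 3L) {
  stopifnot(length(labels) == ncol(rna))
  present <- intersect(gene_ids, rownames(rna))
  if (length(present) == 0) stop("none of the listed genes are in the matrix")
  if (length(present) < length(gene_ids)) {
    flc_log("cluster_means: dropped %d absent gene(s)",
            length(gene_ids) - length(present))
  }
  sizes <- table(labels)
  keep <- sort(names(sizes)[sizes >= min_cells])
  if (length(setdiff(names(sizes), keep))) {
    flc_log("cluster_means: excluded cluster(s) %s below %d cells",
            paste(setdiff(names(sizes), keep), collapse = ","), min_cells)
  }
  norm <- lognormalize(rna)[present, , drop = FALSE]
  out <- vapply(keep, function(k) {
    Matrix::rowMeans(norm[, labels == k, drop = FALSE])
  }, numeric(length(present)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(present),
                                       dimnames = list(present, keep))
  out
}

#' Row-wise z-scoring across clusters
#'
#' Each row is centered at its mean and divided by its sample (n-1)
#' standard deviation; constant rows become all-zero and are flagged in the
#' `constant` attribute rather than dropped.
#'
#' @param means genes x clusters matrix.
#' @return z-score matrix of the same shape, attribute `constant` = logical
#'   per row.
#' @export
zscore_rows <- function(means) {
  if (ncol(means) < 2) stop("z-scoring needs at least 2 clusters")
  mu <- rowMeans(means)
  sd <- apply(means, 1, stats::sd)
  const <- sd == 0
  z <- (means - mu) / ifelse(const, 1, sd)
  z[const, ] <- 0
  attr(z, "constant") <- const
  z
}

#' Affected cell populations
#'
#' A cluster is called "affected" when more than 20% of the projected DEGs
#' have z-score greater than 1 in that cluster; both comparisons are
#' strict, so a cluster at exactly 20% is not affected and a gene at
#' exactly z = 1 does not count.
#'
#' @param z genes x clusters z-score matrix.
#' @param t thresholds (`projection_z_cut`, `projection_deg_frac`).
#' @return data.frame `cluster, fraction, affected`, one row per cluster.
#' @export
affected_populations <- function(z, t = flc_thresholds()) {
  frac <- colMeans(z > t$projection_z_cut)
  data.frame(cluster = colnames(z), fraction = unname(frac),
             affected = unname(frac > t$projection_deg_frac),
             stringsAsFactors = FALSE)
}

#' Gene grouping by dendrogram cut with a minimum group size
#'
#' Rows (genes) are clustered hierarchically (Euclidean, complete linkage)
#' and the tree is cut at the largest k such that no resulting group holds
#' fewer than `ceiling(min_group_frac * n_genes)` genes; if no k >= 2
#' qualifies, a single group is returned.
#'
#' @param z genes x clusters matrix (typically z-scores).
#' @param min_group_frac minimum group size as a fraction of genes
#'   (default 0.02, the study's 2% rule).
#' @return list with `groups` (named integer per gene), `k_selected`, and
#'   `order` (dendrogram leaf order for heatmap export).
#' @export
group_genes <- function(z, min_group_frac = 0.02) {
  n <- nrow(z)
  if (n < 2) stop("grouping needs at least 2 genes")
  d <- stats::dist(z, method = "euclidean")
  if (max(d) == 0) {
    ## indistinguishable rows: any cut would be arbitrary
    return(list(groups = stats::setNames(rep(1L, n), rownames(z)),
                k_selected = 1L, order = seq_len(n)))
  }
  h <- stats::hclust(d, method = "complete")
  min_size <- ceiling(min_group_frac * n)
  k_selected <- 1L
  for (k in 2:n) {
    sizes <- tabulate(stats::cutree(h, k = k))
    if (min(sizes) >= min_size) k_selected <- k
  }
  groups <- if (k_selected == 1L) {
    stats::setNames(rep(1L, n), rownames(z))
  } else {
    stats::cutree(h, k = k_selected)
  }
  list(groups = groups, k_selected = k_selected, order = h$order)
}

#' Bulk-DEG projection onto single-nucleus clusters
#'
#' Runs the empirical-projection chain separately for the up- and
#' down-regulated bulk DEG lists: per-cluster average expression,
#' cross-cluster z-scoring, dendrogram-cut gene grouping under the 2% rule,
#' and the affected-population call. The heatmap export orders genes by
#' dendrogram leaf order and columns by cluster id.
#'
#' @param bulk_de bulk differential table (`feature_id, effect, adj_p,
#'   direction` with `up_in_a` = upregulated).
#' @param rna genes x cells count matrix of the single-nucleus data.
#' @param labels per-cell cluster labels.
#' @param t thresholds.
#' @return named list (`up`, `down`) of projection results: `z`, `groups`,
#'   `k_selected`, `affected`, `heatmap` (ordered z matrix). Directions
#'   with no significant genes are skipped with a warning.
#' @export
project <- function(bulk_de, rna, labels, t = flc_thresholds()) {
  sig <- bulk_de[bulk_de$adj_p < t$adj_p_max, , drop = FALSE]
  lists <- list(up = sig$feature_id[sig$direction == "up_in_a"],
                down = sig$feature_id[sig$direction == "up_in_b"])
  out <- list()
  for (dir in names(lists)) {
    ids <- lists[[dir]]
    if (length(ids) == 0) {
      warning("no significant ", dir, "-regulated genes; direction skipped")
      next
    }
    means <- cluster_means(rna, labels, ids, min_cells = t$min_cluster_cells)
    z <- zscore_rows(means)
    grp <- group_genes(z, min_group_frac = t$projection_min_group_frac)
    out[[dir]] <- list(
      z = z,
      groups = grp$groups,
      k_selected = grp$k_selected,
      affected = affected_populations(z, t),
      heatmap = z[grp$order, sort(colnames(z)), drop = FALSE]
    )
  }
  out
}
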