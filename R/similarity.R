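#' Per-cell depth normalization
#'
#' Counts are divided by each cell's fragment (or count) total and rescaled
#' by the median total, so cells become comparable while the numeric scale
#' stays close to raw counts. The monotone, transparent form keeps every
#' downstream selection oracle-checkable.
#'
#' @param m features x cells sparse or dense matrix.
#' @param depth per-cell totals; defaults to column sums.
#' @return matrix of the same shape with attribute `normalized = TRUE`.
#' @export
normalize_depth <- function(m, depth = NULL) {
  depth <- depth %||% Matrix::colSums(m)
  if (any(depth <= 0)) stop("per-cell depth must be positive")
  out <- m %*% Matrix::Diagonal(x = stats::median(depth) / depth)
  dimnames(out) <- dimnames(m)
  attr(out, "normalized") <- TRUE
  out
}

#' Most variable accessibility peaks
#'
#' Ranks peaks by across-cell variance of depth-normalized signal and keeps
#' the top `n` (the study used the 2000 most variable peaks). Plain variance
#' is used rather than a fitted dispersion model: the downstream use
#' (cluster distance ranking) is robust to the selector and variance is
#' fully oracle-testable. Ties break deterministically by peak id.
#'
#' @param atac peaks x cells matrix (raw counts or 0/1 signal).
#' @param n number of peaks to keep.
#' @param depth per-cell fragment totals used for normalization.
#' @return character vector of selected peak ids.
#' @export
select_variable_peaks <- function(atac, n, depth = NULL) {
  if (is.null(rownames(atac))) stop("atac matrix needs rownames (peak ids)")
  norm <- normalize_depth(atac, depth)
  v <- row_vars(norm)
  if (n > length(v)) {
    flc_log("select_variable_peaks: n=%d exceeds %d peaks; returning all",
            n, length(v))
    n <- length(v)
  }
  ord <- order(-v, rownames(atac))
  rownames(atac)[ord[seq_len(n)]]
}

## Row variances of a (possibly sparse) matrix, n-1 denominator.
row_vars <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  (Matrix::rowSums(m^2) - n * mu^2) / (n - 1)
}

#' Cluster-to-cluster chromatin distance
#'
#' Averages depth-normalized accessibility per cluster over the selected
#' peaks and returns the pairwise Euclidean distance matrix between cluster
#' mean profiles. Clusters with fewer than `min_cells` cells are excluded
#' (the study dropped its 2-cell cluster).
#'
#' @param atac peaks x cells matrix.
#' @param labels per-cell cluster labels (along columns of `atac`).
#' @param peaks peak ids defining the profile (e.g. from
#'   [select_variable_peaks()]).
#' @param depth per-cell fragment totals.
#' @param min_cells minimum cluster size.
#' @return symmetric distance matrix with cluster ids as dimnames and a
#'   `profiles` attribute holding the mean-signal matrix (peaks x clusters).
#' @export
cluster_distances <- function(atac, labels, peaks = rownames(atac),
                              depth = NULL, min_cells = 3L) {
  stopifnot(length(labels) == ncol(atac))
  norm <- normalize_depth(atac, depth)[peaks, , drop = FALSE]
  sizes <- table(labels)
  keep <- names(sizes)[sizes >= min_cells]
  drop <- setdiff(names(sizes), keep)
  if (length(drop)) {
    flc_log("cluster_distances: excluded %s (fewer than %d cells)",
            paste(drop, collapse = ","), min_cells)
  }
  if (length(keep) < 2) stop("need >= 2 clusters passing min_cells")
  keep <- sort(keep)
  prof <- vapply(keep, function(k) {
    Matrix::rowMeans(norm[, labels == k, drop = FALSE])
  }, numeric(length(peaks)))
  d <- as.matrix(stats::dist(t(prof), method = "euclidean"))
  attr(d, "profiles") <- prof
  attr(d, "n_cells") <- as.integer(sizes[keep])
  d
}

#' Dendrogram from a cluster distance matrix
#'
#' Agglomerative hierarchical clustering of the cluster profiles (complete
#' linkage by default, configurable). Merge heights are non-decreasing.
#'
#' @param d symmetric distance matrix (e.g. from [cluster_distances()]).
#' @param method linkage: `"complete"`, `"average"` or `"single"`.
#' @return an [stats::hclust] object.
#' @export
build_dendrogram <- function(d, method = c("complete", "average", "single")) {
  method <- match.arg(method)
  if (nrow(d) < 2) stop("need >= 2 clusters to build a dendrogram")
  stats::hclust(stats::as.dist(d), method = method)
}

#' Newick export of a dendrogram
#'
#' @param h an [stats::hclust] object.
#' @return single Newick string.
#' @export
dendrogram_newick <- function(h) {
  ape::write.tree(ape::as.phylo(h))
}

#' Nearest cluster by chromatin distance
#'
#' Argmin of the distance from `target` to every other cluster; ties break
#' by cluster id order. This is the query behind the study's identification
#' of the progenitor cluster as the nearest neighbor of the fetal Leydig
#' cluster.
#'
#' @param d distance matrix with cluster ids as dimnames.
#' @param target cluster id present in `d`.
#' @return list with `cluster` (id) and `distance`.
#' @export
nearest_cluster <- function(d, target) {
  if (!target %in% rownames(d)) stop("cluster not in distance matrix: ", target)
  others <- setdiff(sort(rownames(d)), target)
  dv <- d[target, others]
  i <- which.min(dv) # first minimum = tie-break by sorted cluster id
  list(cluster = others[i], distance = unname(dv[i]))
}
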