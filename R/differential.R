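#' Log-normalization of RNA counts
#'
#' Counts per cell are scaled to a common total of 10,000 and transformed
#' with `log1p` -- the conventional single-cell normalization implied by the
#' study's toolchain.
#'
#' @param m genes x cells count matrix.
#' @return dense-ish sparse matrix of log-normalized expression.
#' @export
lognormalize <- function(m) {
  tot <- Matrix::colSums(m)
  if (any(tot <= 0)) stop("cells with zero total counts cannot be normalized")
  out <- m %*% Matrix::Diagonal(x = 1e4 / tot)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(m)
  attr(out, "normalized") <- TRUE
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value vector (delegates to
#' [stats::p.adjust()]); exposed as the single correction point shared by
#' every differential table in the pipeline.
#'
#' @param p p-values in \[0,1\].
#' @return adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

new_differential_table <- function(feature_id, group_a, group_b, effect, p) {
  adj_p <- bh_adjust(p)
  data.frame(
    feature_id = feature_id,
    group_a = group_a,
    group_b = group_b,
    effect = effect,
    p = p,
    adj_p = adj_p,
    direction = ifelse(effect >= 0, "up_in_a", "up_in_b"),
    stringsAsFactors = FALSE
  )
}

#' Differential expression between two clusters
#'
#' Two-sided Wilcoxon rank-sum test per gene on log-normalized counts, with
#' BH correction over all tested genes; a gene is significant at
#' `adj_p < 0.05` (strict). The effect is the log2 ratio of mean normalized
#' expression (pseudocount 1). Genes with identical values in every cell of
#' both groups get `p = 1`, `effect = 0`.
#'
#' @param rna genes x cells raw count matrix.
#' @param labels per-cell cluster labels.
#' @param a,b the two cluster ids to contrast (effect sign: positive =
#'   higher in `a`).
#' @param t thresholds (only `min_cluster_cells` and `adj_p_max` are used).
#' @return a differential table (one row per gene) with columns
#'   `feature_id, group_a, group_b, effect, p, adj_p, direction`.
#' @export
de_test <- function(rna, labels, a, b, t = flc_thresholds()) {
  stopifnot(length(labels) == ncol(rna))
  ia <- which(labels == a); ib <- which(labels == b)
  if (length(ia) < t$min_cluster_cells || length(ib) < t$min_cluster_cells) {
    stop("both clusters must have at least ", t$min_cluster_cells, " cells")
  }
  norm <- lognormalize(rna)
  xa <- as.matrix(norm[, ia, drop = FALSE])
  xb <- as.matrix(norm[, ib, drop = FALSE])
  res <- vapply(seq_len(nrow(rna)), function(g) {
    va <- xa[g, ]; vb <- xb[g, ]
    ## expm1 undoes the log so the fold change is on the normalized scale
    eff <- log2((mean(expm1(va)) + 1) / (mean(expm1(vb)) + 1))
    if (stats::var(c(va, vb)) == 0) {
      return(c(eff = 0, p = 1))
    }
    p <- stats::wilcox.test(va, vb, alternative = "two.sided",
                            exact = FALSE, correct = TRUE)$p.value
    c(eff = eff, p = p)
  }, numeric(2))
  new_differential_table(rownames(rna) %||% as.character(seq_len(nrow(rna))),
                         a, b, res["eff", ], res["p", ])
}

#' Differential accessibility between two clusters
#'
#' Logistic-regression likelihood-ratio test with a fragment-depth
#' covariate, mirroring the study's latent-variable design: for each peak,
#' cluster membership is modeled as `group ~ peak_signal + fragment_total`
#' and compared against the covariate-only model by a chi-square LRT
#' (1 d.f.). A peak whose apparent accessibility difference is driven
#' purely by sequencing depth is therefore not called. Effect size is the
#' log2 ratio of open rates with a small-sample shrinkage constant
#' `eps = 1/(n_a + n_b)`.
#'
#' @param atac peaks x cells matrix; any positive entry counts as open.
#' @param labels per-cell cluster labels.
#' @param a,b cluster ids to contrast.
#' @param covariate per-cell fragment totals (positive), along columns of
#'   `atac`.
#' @param t thresholds.
#' @return differential table with one row per tested peak; peaks closed in
#'   every cell of both groups are skipped (logged).
#' @export
da_test <- function(atac, labels, a, b, covariate, t = flc_thresholds()) {
  stopifnot(length(labels) == ncol(atac), length(covariate) == ncol(atac))
  if (any(covariate <= 0)) stop("fragment covariate must be positive")
  sel <- labels %in% c(a, b)
  ia <- labels[sel] == a
  x <- as.matrix(atac[, sel, drop = FALSE]) > 0
  storage.mode(x) <- "double"
  if (sum(ia) < t$min_cluster_cells || sum(!ia) < t$min_cluster_cells) {
    stop("both clusters must have at least ", t$min_cluster_cells, " cells")
  }
  cov <- covariate[sel]
  y <- as.numeric(ia)
  n_a <- sum(ia); n_b <- sum(!ia)
  eps <- 1 / (n_a + n_b)
  ## reduced (covariate-only) model is shared by all peaks
  fit0 <- stats::glm(y ~ cov, family = stats::binomial())
  dev0 <- fit0$deviance
  tested <- which(rowSums(x) > 0)
  skipped <- nrow(x) - length(tested)
  if (skipped > 0) flc_log("da_test: skipped %d all-closed peak(s)", skipped)
  res <- vapply(tested, function(p) {
    xp <- x[p, ]
    rate_a <- mean(xp[ia]); rate_b <- mean(xp[!ia])
    eff <- log2((rate_a + eps) / (rate_b + eps))
    if (stats::var(xp) == 0) {
      return(c(eff = eff, p = 1))
    }
    fit1 <- suppressWarnings(
      stats::glm(y ~ xp + cov, family = stats::binomial())
    )
    lr <- max(dev0 - fit1$deviance, 0)
    c(eff = eff, p = stats::pchisq(lr, df = 1, lower.tail = FALSE))
  }, numeric(2))
  ids <- (rownames(atac) %||% as.character(seq_len(nrow(atac))))[tested]
  new_differential_table(ids, a, b, res["eff", ], res["p", ])
}

#' Significant features of a differential table
#'
#' @param tab differential table.
#' @param side optional: keep only features up in this cluster id.
#' @param adj_p_max strict significance threshold on the BH-adjusted p.
#' @return subset of `tab`.
#' @export
significant_features <- function(tab, side = NULL, adj_p_max = 0.05) {
  out <- tab[tab$adj_p < adj_p_max, , drop = FALSE]
  if (!is.null(side)) {
    dir <- ifelse(out$group_a == side, "up_in_a",
                  ifelse(out$group_b == side, "up_in_b", NA))
    out <- out[!is.na(dir) & out$direction == dir, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
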