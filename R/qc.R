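#' Per-cell RNA quality gate
#'
#' A cell passes iff mitochondrial fraction < 10%, ribosomal fraction < 10%,
#' hemoglobin fraction < 0.5% and more than 500 detected genes. Every
#' comparison is strict, following the study's wording: a cell at exactly
#' 10% mitochondrial content fails.
#'
#' @param cells data.frame with columns `cell_id`, `pct_mito`, `pct_ribo`,
#'   `pct_hemo`, `n_genes_detected` (fractions on \[0,1\]).
#' @param t an [flc_thresholds()] object.
#' @return logical pass mask along rows of `cells`.
#' @export
rna_pass <- function(cells, t = flc_thresholds()) {
  need <- c("pct_mito", "pct_ribo", "pct_hemo", "n_genes_detected")
  check_cell_metrics(cells, need)
  cells$pct_mito < t$rna_mito_max &
    cells$pct_ribo < t$rna_ribo_max &
    cells$pct_hemo < t$rna_hemo_max &
    cells$n_genes_detected > t$rna_min_genes
}

#' Per-cell ATAC quality gate
#'
#' A cell passes iff its fraction of reads in peaks exceeds 20%, its
#' fragment count in peaks lies strictly between 250 and 25,000, and fewer
#' than 5% of its fragments fall in blacklist regions. All comparisons
#' strict: 250 fragments is a failure.
#'
#' @param cells data.frame with columns `cell_id`, `frip`,
#'   `n_frag_in_peaks`, `pct_blacklist`.
#' @inheritParams rna_pass
#' @return logical pass mask.
#' @export
atac_pass <- function(cells, t = flc_thresholds()) {
  need <- c("frip", "n_frag_in_peaks", "pct_blacklist")
  check_cell_metrics(cells, need)
  cells$frip > t$atac_frip_min &
    cells$n_frag_in_peaks > t$atac_frag_min &
    cells$n_frag_in_peaks < t$atac_frag_max &
    cells$pct_blacklist < t$atac_blacklist_max
}

check_cell_metrics <- function(cells, need) {
  miss <- setdiff(c("cell_id", need), names(cells))
  if (length(miss)) stop("cell table lacks column(s): ", paste(miss, collapse = ", "))
  for (f in need) {
    na <- which(is.na(cells[[f]]))
    if (length(na)) {
      stop(sprintf("missing QC metric '%s' for cell %s", f, cells$cell_id[na[1]]))
    }
  }
  invisible(TRUE)
}

#' Joint RNA + ATAC cell filter
#'
#' Cells are retained only when they pass both assay gates. The attached
#' `qc_report` attribute counts failures per criterion (a cell can fail
#' several).
#'
#' @inheritParams rna_pass
#' @return the retained rows of `cells`, with attribute `qc_report`.
#' @export
joint_filter <- function(cells, t = flc_thresholds()) {
  rna <- rna_pass(cells, t)
  atac <- atac_pass(cells, t)
  keep <- rna & atac
  report <- data.frame(
    criterion = c("pct_mito", "pct_ribo", "pct_hemo", "n_genes_detected",
                  "frip", "n_frag_in_peaks_low", "n_frag_in_peaks_high",
                  "pct_blacklist"),
    n_fail = c(sum(cells$pct_mito >= t$rna_mito_max),
               sum(cells$pct_ribo >= t$rna_ribo_max),
               sum(cells$pct_hemo >= t$rna_hemo_max),
               sum(cells$n_genes_detected <= t$rna_min_genes),
               sum(cells$frip <= t$atac_frip_min),
               sum(cells$n_frag_in_peaks <= t$atac_frag_min),
               sum(cells$n_frag_in_peaks >= t$atac_frag_max),
               sum(cells$pct_blacklist >= t$atac_blacklist_max)),
    stringsAsFactors = FALSE
  )
  flc_log("joint_filter: retained %d of %d cells", sum(keep), nrow(cells))
  out <- cells[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_report") <- report
  out
}
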