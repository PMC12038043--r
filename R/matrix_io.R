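#' Read a feature-by-cell count matrix
#'
#' MatrixMarket triplet reader in the 10x layout: a coordinate `.mtx` file
#' plus one-column TSVs of feature ids (rows) and cell barcodes (columns).
#' The result is a sparse `dgCMatrix` with dimnames set and a `normalized`
#' attribute flag of `FALSE` (raw counts).
#'
#' @param mtx path to the MatrixMarket file.
#' @param features path to the feature-id TSV (one id per line).
#' @param barcodes path to the barcode TSV (one id per line).
#' @return sparse matrix, features x cells.
#' @export
read_matrix <- function(mtx, features, barcodes) {
  for (p in c(mtx, features, barcodes)) {
    if (!file.exists(p)) stop("matrix input not found: ", p)
  }
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  feat <- utils::read.delim(features, header = FALSE,
                            stringsAsFactors = FALSE)[[1]]
  bc <- utils::read.delim(barcodes, header = FALSE,
                          stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(feat)) {
    stop(sprintf("format error: %s declares %d rows but %s has %d features",
                 mtx, nrow(m), features, length(feat)))
  }
  if (ncol(m) != length(bc)) {
    stop(sprintf("format error: %s declares %d columns but %s has %d barcodes",
                 mtx, ncol(m), barcodes, length(bc)))
  }
  dimnames(m) <- list(feat, bc)
  attr(m, "normalized") <- FALSE
  m
}

#' Write a feature-by-cell matrix
#'
#' Inverse of [read_matrix()]: writes the MTX triplets plus the feature and
#' barcode TSVs. Round-trips are triplet-exact for integer count matrices.
#'
#' @param m a sparse matrix with dimnames.
#' @param mtx,features,barcodes output paths.
#' @return `invisible(NULL)`.
#' @export
write_matrix <- function(m, mtx, features, barcodes) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  Matrix::writeMM(methods::as(m, "TsparseMatrix"), mtx)
  writeLines(rownames(m), features)
  writeLines(colnames(m), barcodes)
  invisible(NULL)
}
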