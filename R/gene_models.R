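#' Gene model table
#'
#' Minimal strand-aware gene model: chromosome, gene body `[start, end)`
#' in 0-based half-open coordinates, strand and a unique gene id. The TSS
#' is derived when not supplied: `start` for `+` genes and `end - 1` for
#' `-` genes (the last base inside the half-open body).
#'
#' @param chrom,start,end,strand,gene_id equal-length vectors.
#' @param tss optional explicit TSS positions.
#' @return `data.frame` of class `gene_models`.
#' @export
#' @examples
#' gene_models("chr1", 1000, 5000, "+", "GeneA")$tss  # 1000
#' gene_models("chr1", 1000, 5000, "-", "GeneB")$tss  # 4999
gene_models <- function(chrom, start, end, strand, gene_id, tss = NULL) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  strand <- as.character(strand)
  gene_id <- as.character(gene_id)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(start >= end)) stop("gene body start must be < end")
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup)) {
    stop("duplicate gene_id(s): ", paste(dup, collapse = ", "))
  }
  if (is.null(tss)) {
    tss <- ifelse(strand == "+", start, end - 1L)
  }
  df <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                   gene_id = gene_id, tss = as.integer(tss),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read / write gene models
#'
#' TSV with header `chrom start end strand gene_id [tss]`; coordinates are
#' 0-based half-open. TSS is derived from strand when the column is absent.
#'
#' @param path file location.
#' @param genes a `gene_models` table (for writing).
#' @return `read_gene_models()` returns a [gene_models()] table.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  df <- read_tsv_file(path)
  need <- c("chrom", "start", "end", "strand", "gene_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("gene model file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  gene_models(df$chrom, df$start, df$end, df$strand, df$gene_id,
              tss = if ("tss" %in% names(df)) df$tss else NULL)
}

#' @rdname read_gene_models
#' @export
write_gene_models <- function(genes, path) {
  stopifnot(inherits(genes, "gene_models"))
  write_tsv_file(as.data.frame(genes), path)
}
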