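#' Ordered genomic interval set
#'
#' Lightweight container for named genomic intervals in BED convention:
#' 0-based, half-open `[start, end)`. All coordinates in the package use this
#' single convention; 1-based dialects are converted at the boundary (only
#' inside the GenomicRanges bridge used for overlap arithmetic).
#'
#' @param chrom,start,end,name vectors of equal length; `name` optional
#'   (auto-generated as `peak_<i>` after sorting when missing).
#' @return a `data.frame` of class `interval_set`, sorted by
#'   (chrom, start, end).
#' @export
#' @examples
#' interval_set("chr1", 100, 500)
interval_set <- function(chrom, start, end, name = NULL) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop(sprintf("coordinate error: start >= end at record %d (%s:%d-%d)",
                 bad, chrom[bad], start[bad], end[bad]))
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  ord <- order(df$chrom, df$start, df$end)
  df <- df[ord, , drop = FALSE]
  if (is.null(name)) {
    df$name <- if (nrow(df)) paste0("peak_", seq_len(nrow(df))) else character(0)
  } else {
    df$name <- as.character(name)[ord]
  }
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  df
}

#' Read a BED file
#'
#' BED3+ reader; column 4, when present, is kept as the interval name.
#' Records on chromosomes outside `genome` (when given) are dropped with a
#' logged count; a record with `start >= end` is a hard coordinate error.
#'
#' @param path BED file location.
#' @param genome optional character vector of allowed chromosome names.
#' @return an [interval_set()].
#' @export
read_intervals <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(raw) < 3) stop("format error in ", path, ": BED needs >= 3 columns")
  chrom <- as.character(raw[[1]])
  start <- as.integer(raw[[2]])
  end <- as.integer(raw[[3]])
  name <- if (ncol(raw) >= 4) as.character(raw[[4]]) else NULL
  if (!is.null(genome)) {
    keep <- chrom %in% genome
    if (any(!keep)) {
      flc_log("read_intervals: dropped %d record(s) on non-canonical chromosomes",
              sum(!keep))
    }
    chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
    if (!is.null(name)) name <- name[keep]
  }
  interval_set(chrom, start, end, name)
}

#' Write a BED file
#'
#' @param x an [interval_set()].
#' @param path output location.
#' @return the path, invisibly.
#' @export
write_intervals <- function(x, path) {
  stopifnot(inherits(x, "interval_set"))
  utils::write.table(x[, c("chrom", "start", "end", "name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

## Bridge to GenomicRanges for overlap arithmetic. BED half-open [s, e)
## becomes 1-based closed [s+1, e]; widths are preserved exactly.
as_granges <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    name = x$name
  )
}

#' Interval overlap queries
#'
#' `overlaps_any()` flags, for each query interval, whether it shares at
#' least 1 bp with any subject interval; `count_interval_overlaps()` counts
#' the overlapping subjects. Both use half-open semantics: abutting
#' intervals do not overlap.
#'
#' @param query,subject [interval_set()] objects.
#' @return logical (or integer) vector along `query`.
#' @export
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  ## cross-chromosome queries are legitimate; silence the no-common-levels note
  suppressWarnings(IRanges::overlapsAny(as_granges(query), as_granges(subject)))
}

#' @rdname overlaps_any
#' @export
count_interval_overlaps <- function(query, subject) {
  if (nrow(query) == 0) return(integer(0))
  if (nrow(subject) == 0) return(rep(0L, nrow(query)))
  suppressWarnings(
    GenomicRanges::countOverlaps(as_granges(query), as_granges(subject))
  )
}
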