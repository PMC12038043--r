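#' Resize peaks to a fixed width around their midpoints
#'
#' Each interval becomes `[mid - floor(w/2), mid + ceiling(w/2))` with
#' `mid = floor((start + end) / 2)`, exactly the study's 300 bp re-centering
#' of called ChIP peaks. Output intervals are clipped at 0 and, when
#' chromosome lengths are supplied, at the chromosome end; clipping is
#' logged.
#'
#' @param peaks an [interval_set()].
#' @param width target width in bp.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return resized [interval_set()] (names preserved).
#' @export
#' @examples
#' p <- interval_set("chr1", 100, 500, "p1")
#' resize_peaks(p, 300) # [150, 450)
resize_peaks <- function(peaks, width, chrom_lengths = NULL) {
  stopifnot(inherits(peaks, "interval_set"), width > 0)
  mid <- (peaks$start + peaks$end) %/% 2L
  s <- mid - width %/% 2L
  e <- mid + as.integer(ceiling(width / 2))
  clipped <- s < 0
  s[s < 0] <- 0L
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[peaks$chrom]
    over <- !is.na(len) & e > len
    e[over] <- as.integer(len[over])
    clipped <- clipped | over
  }
  if (any(clipped)) {
    flc_log("resize_peaks: clipped %d peak(s) at chromosome bounds",
            sum(clipped))
  }
  interval_set(peaks$chrom, s, e, peaks$name)
}

#' Blacklist and canonical-chromosome peak filter
#'
#' Retains peaks that overlap no blacklist interval by even 1 bp and sit on
#' an allowed chromosome. Half-open semantics: a peak abutting a blacklist
#' region is retained.
#'
#' @param peaks,blacklist [interval_set()] objects.
#' @param genome allowed chromosome names (`NULL` skips the chromosome
#'   filter).
#' @return filtered [interval_set()].
#' @export
filter_peaks <- function(peaks, blacklist = NULL, genome = canonical_chromosomes()) {
  stopifnot(inherits(peaks, "interval_set"))
  keep <- rep(TRUE, nrow(peaks))
  if (!is.null(genome)) keep <- keep & peaks$chrom %in% genome
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    keep <- keep & !overlaps_any(peaks, blacklist)
  }
  flc_log("filter_peaks: retained %d of %d peaks", sum(keep), nrow(peaks))
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Genomic-context classification relative to the nearest TSS
#'
#' For each peak midpoint, the nearest gene is the one whose TSS minimizes
#' `|midpoint - TSS|` on the same chromosome (equidistant ties break by
#' lexicographic gene id, logged). The signed distance is taken in gene
#' orientation (negative = upstream of the TSS). Classes are exclusive with
#' precedence promoter > gene body > upstream > intergenic:
#' promoter when the signed distance lies in `[-1000, 0]` (a midpoint
#' exactly at the TSS counts as promoter), gene body when the midpoint
#' falls inside the gene body `[start, end)`, upstream when the signed
#' distance lies in `[-10000, -1000)`, intergenic otherwise (including
#' peaks on chromosomes without genes).
#'
#' @param peaks an [interval_set()] (typically resized ChIP peaks).
#' @param genes a [gene_models()] table.
#' @param t thresholds (`promoter_upstream`, `upstream_window`).
#' @return data.frame of annotated peaks: interval columns plus `midpoint`,
#'   `nearest_gene`, `signed_distance_to_tss`, `context`.
#' @export
classify_context <- function(peaks, genes, t = flc_thresholds()) {
  stopifnot(inherits(peaks, "interval_set"), inherits(genes, "gene_models"))
  mid <- (peaks$start + peaks$end) %/% 2L
  n <- nrow(peaks)
  nearest <- character(n)
  sdist <- rep(NA_integer_, n)
  context <- rep("intergenic", n)
  tie_count <- 0L
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) {
      nearest[i] <- NA_character_
      next
    }
    ad <- abs(mid[i] - g$tss)
    hits <- which(ad == min(ad))
    if (length(hits) > 1) {
      hits <- hits[order(g$gene_id[hits])]
      tie_count <- tie_count + 1L
    }
    j <- hits[1]
    nearest[i] <- g$gene_id[j]
    d <- if (g$strand[j] == "+") mid[i] - g$tss[j] else g$tss[j] - mid[i]
    sdist[i] <- d
    in_body <- mid[i] >= g$start[j] && mid[i] < g$end[j]
    context[i] <-
      if (d >= -t$promoter_upstream && d <= 0) "promoter"
      else if (in_body) "gene_body"
      else if (d >= -t$upstream_window && d < -t$promoter_upstream) "upstream"
      else "intergenic"
  }
  if (tie_count > 0) {
    flc_log("classify_context: %d equidistant-TSS tie(s) broken by gene id",
            tie_count)
  }
  data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
             name = peaks$name, midpoint = mid, nearest_gene = nearest,
             signed_distance_to_tss = sdist, context = context,
             stringsAsFactors = FALSE)
}

#' Context composition of an annotated peak set
#'
#' Percentages of peaks in each of the four genomic-context classes,
#' reported to the nearest integer (the form in which the study prints its
#' 35/34/26/5 split).
#'
#' @param annotated output of [classify_context()].
#' @return named numeric vector over
#'   `promoter, gene_body, upstream, intergenic`.
#' @export
context_composition <- function(annotated) {
  stopifnot(nrow(annotated) > 0)
  classes <- c("promoter", "gene_body", "upstream", "intergenic")
  counts <- vapply(classes, function(k) sum(annotated$context == k), integer(1))
  round(100 * counts / sum(counts))
}
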