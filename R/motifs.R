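#' JASPAR PFM reader
#'
#' Parses JASPAR-format position frequency matrices: a `>motif_id name`
#' header followed by four base rows, in either the bracketed dialect
#' (`A [ 4 19 0 ]`) or plain whitespace-separated counts. The second header
#' token is kept as the TF gene id for the motif.
#'
#' @param path PFM text file (may hold several motifs).
#' @return named list of motifs; each motif is a list with `motif_id`,
#'   `tf_gene_id` and `pfm` (4 x L matrix, rows A,C,G,T).
#' @export
read_jaspar <- function(path) {
  if (!file.exists(path)) stop("PFM file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no motif headers in ", path)
  out <- list()
  for (i in seq_along(heads)) {
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    block <- lines[(heads[i] + 1):to]
    if (length(block) < 4) stop("motif block with fewer than 4 rows in ", path)
    toks <- strsplit(sub("^>\\s*", "", lines[heads[i]]), "\\s+")[[1]]
    motif_id <- toks[1]
    tf <- if (length(toks) >= 2) toks[2] else toks[1]
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("^[ACGTacgt]", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    L <- unique(lengths(rows))
    if (length(L) != 1) stop("ragged PFM rows for motif ", motif_id)
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- c("A", "C", "G", "T")
    out[[motif_id]] <- flc_motif(motif_id, tf, pfm)
  }
  out
}

#' Motif model
#'
#' @param motif_id,tf_gene_id identifiers.
#' @param pfm 4 x L matrix (rows A,C,G,T) of counts or probabilities.
#' @return list of class `flc_motif`.
#' @export
flc_motif <- function(motif_id, tf_gene_id, pfm) {
  stopifnot(nrow(pfm) == 4, ncol(pfm) >= 4)
  rownames(pfm) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, tf_gene_id = tf_gene_id, pfm = pfm),
            class = "flc_motif")
}

#' Log-odds matrix of a motif
#'
#' Column-normalized probabilities (with a pseudocount) scored against the
#' uniform background, in log2 units. Probability-form PFMs are rescaled to
#' pseudo-counts of 100 before the pseudocount is applied, so both JASPAR
#' dialects behave identically.
#'
#' @param motif an [flc_motif()].
#' @param pseudocount total pseudocount per column.
#' @return 4 x L numeric matrix.
#' @export
motif_logodds <- function(motif, pseudocount = 1) {
  pfm <- motif$pfm
  cs <- colSums(pfm)
  if (all(abs(cs - 1) < 1e-6)) pfm <- pfm * 100
  prob <- sweep(pfm + pseudocount / 4, 2, colSums(pfm) + pseudocount, "/")
  log2(prob / 0.25)
}

#' Consensus sequence of a motif
#'
#' Highest-probability base per column (ties to the earlier base in
#' A,C,G,T order).
#'
#' @param motif an [flc_motif()].
#' @return character scalar over A,C,G,T.
#' @export
motif_consensus <- function(motif) {
  paste(rownames(motif$pfm)[apply(motif$pfm, 2, which.max)], collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", vapply(strsplit(s, NULL),
                                function(x) paste(rev(x), collapse = ""),
                                character(1)))
}

## Score all windows of one sequence (integer-coded) against a log-odds
## matrix; returns numeric(0) when the sequence is shorter than the motif.
score_windows <- function(codes, lo) {
  L <- ncol(lo)
  n <- length(codes)
  if (n < L) return(numeric(0))
  starts <- seq_len(n - L + 1)
  sc <- numeric(length(starts))
  for (j in seq_len(L)) {
    sc <- sc + lo[cbind(codes[starts + j - 1], j)]
  }
  sc
}

#' Scan sequences for motif occurrences
#'
#' A hit is any window, on either strand, whose log-odds score reaches
#' `threshold_frac` of the maximum attainable score for the motif (default
#' 0.8). Offsets are 0-based window starts on the forward strand.
#' Sequences shorter than the motif yield no hit (logged).
#'
#' @param sequences named character vector of peak sequences (A,C,G,T).
#' @param motif an [flc_motif()].
#' @param threshold_frac fraction of the maximum log-odds score in (0, 1].
#' @return list with `hits` (named logical per sequence) and `sites`
#'   (data.frame `seq_id, offset, strand, score`).
#' @export
scan_motif <- function(sequences, motif, threshold_frac = 0.8) {
  stopifnot(threshold_frac > 0, threshold_frac <= 1)
  lo <- motif_logodds(motif)
  max_score <- sum(apply(lo, 2, max))
  cut <- threshold_frac * max_score
  ## reverse-complement scan: reverse the columns and swap complementary rows
  lo_rc <- lo[c("T", "G", "C", "A"), rev(seq_len(ncol(lo))), drop = FALSE]
  rownames(lo_rc) <- c("A", "C", "G", "T")
  code <- function(s) match(strsplit(s, NULL)[[1]], c("A", "C", "G", "T"))
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  short <- 0L
  sites <- vector("list", length(sequences))
  hits <- logical(length(sequences))
  for (i in seq_along(sequences)) {
    codes <- code(sequences[[i]])
    if (length(codes) < ncol(lo)) {
      short <- short + 1L
      next
    }
    fw <- score_windows(codes, lo)
    rv <- score_windows(codes, lo_rc)
    hf <- which(fw >= cut)
    hr <- which(rv >= cut)
    if (length(hf) || length(hr)) {
      hits[i] <- TRUE
      sites[[i]] <- data.frame(
        seq_id = ids[i],
        offset = c(hf, hr) - 1L,
        strand = rep(c("+", "-"), c(length(hf), length(hr))),
        score = c(fw[hf], rv[hr]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (short > 0) flc_log("scan_motif: %d sequence(s) shorter than motif", short)
  names(hits) <- ids
  sites <- if (any(hits)) do.call(rbind, sites[!vapply(sites, is.null, logical(1))])
           else data.frame(seq_id = character(0), offset = integer(0),
                           strand = character(0), score = numeric(0))
  list(hits = hits, sites = sites)
}

#' Hit matrix over a motif collection
#'
#' @param sequences named character vector.
#' @param motifs list of [flc_motif()] objects.
#' @param threshold_frac see [scan_motif()].
#' @return logical matrix, sequences x motifs.
#' @export
scan_motifs <- function(sequences, motifs, threshold_frac = 0.8) {
  m <- vapply(motifs, function(mo) scan_motif(sequences, mo, threshold_frac)$hits,
              logical(length(sequences)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(sequences))
  rownames(m) <- names(sequences)
  colnames(m) <- vapply(motifs, `[[`, character(1), "motif_id")
  m
}

#' Motif enrichment in foreground vs background peaks
#'
#' One-sided hypergeometric test per motif on the 2x2 table of
#' foreground/background by with/without motif, BH-adjusted over motifs.
#' Fold enrichment is the ratio of with-motif fractions; when the
#' background carries no hit but the foreground does, the fold is reported
#' as `Inf` while the p-value stays exact.
#'
#' @param fg_ids,bg_ids disjoint character vectors of peak ids.
#' @param hits logical matrix from [scan_motifs()] covering all ids.
#' @param motifs the motif list (for the TF gene mapping).
#' @return data.frame, one row per motif: counts, `fold_enrichment`, `p`,
#'   `adj_p`.
#' @export
enrich_motifs <- function(fg_ids, bg_ids, hits, motifs = NULL) {
  if (length(intersect(fg_ids, bg_ids))) {
    stop("foreground and background peak sets must be disjoint")
  }
  stopifnot(all(c(fg_ids, bg_ids) %in% rownames(hits)))
  tf_map <- if (!is.null(motifs)) {
    stats::setNames(vapply(motifs, `[[`, character(1), "tf_gene_id"),
                    vapply(motifs, `[[`, character(1), "motif_id"))
  }
  nf <- length(fg_ids); nb <- length(bg_ids)
  fw <- Matrix::colSums(hits[fg_ids, , drop = FALSE])
  bw <- Matrix::colSums(hits[bg_ids, , drop = FALSE])
  p <- stats::phyper(fw - 1, fw + bw, nf + nb - fw - bw, nf,
                     lower.tail = FALSE)
  fold <- ifelse(bw == 0 & fw > 0, Inf,
                 ifelse(bw == 0, NA_real_, (fw / nf) / (bw / nb)))
  mid <- colnames(hits)
  out <- data.frame(
    motif_id = mid,
    tf_gene_id = if (!is.null(tf_map)) unname(tf_map[mid]) else mid,
    n_fg_with = unname(fw), n_fg = nf, n_bg_with = unname(bw), n_bg = nb,
    fold_enrichment = unname(fold), p = unname(p),
    stringsAsFactors = FALSE
  )
  out$adj_p <- bh_adjust(out$p)
  out
}

#' GC fraction of sequences
#'
#' @param sequences character vector.
#' @return numeric fraction of G/C bases per sequence.
#' @export
gc_content <- function(sequences) {
  vapply(sequences, function(s) {
    b <- strsplit(s, NULL)[[1]]
    mean(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = !is.null(names(sequences)))
}

#' GC-matched background sampling
#'
#' Samples background peaks so their GC histogram (bins of width 0.05)
#' matches the foreground's. Bins whose candidate pool is too small fall
#' back to sampling from the whole pool (logged). Sampling uses the
#' session RNG; seed upstream for reproducibility.
#'
#' @param fg_ids foreground peak ids.
#' @param pool_ids candidate background ids (disjoint from foreground).
#' @param sequences named sequences covering both sets.
#' @param bin_width GC bin width.
#' @return character vector of sampled background ids.
#' @export
gc_matched_background <- function(fg_ids, pool_ids, sequences, bin_width = 0.05) {
  gc <- gc_content(sequences)
  binify <- function(x) pmin(floor(x / bin_width), floor(1 / bin_width) - 1)
  fg_bins <- binify(gc[fg_ids])
  pool_bins <- binify(gc[pool_ids])
  out <- character(0)
  fallback <- FALSE
  for (b in sort(unique(fg_bins))) {
    need <- sum(fg_bins == b)
    avail <- pool_ids[pool_bins == b]
    if (length(avail) < need) {
      fallback <- TRUE
      break
    }
    out <- c(out, sample(avail, need))
  }
  if (fallback) {
    flc_log("gc_matched_background: empty/short GC bin; using full pool")
    return(pool_ids)
  }
  out
}

#' Combined TF candidate ranking
#'
#' Candidate transcription factors are those with motif enrichment
#' `adj_p < 0.05` and differential expression `adj_p < 0.05` upregulated on
#' the given cluster side. The combination of the two criteria is
#' operationalized as a rank-sum: each TF is ranked by ascending motif
#' adjusted p and by ascending DE adjusted p, and the final order is the
#' rank of the sum (ties by motif adjusted p, then gene id). Rank-sum is
#' scale-free, so any monotone transform of either p-value column leaves
#' the ordering unchanged.
#'
#' @param enrichment output of [enrich_motifs()].
#' @param de differential table for the same cluster contrast.
#' @param side cluster id whose upregulated TFs are eligible.
#' @param adj_p_max strict threshold applied to both criteria.
#' @return data.frame `tf_gene_id, motif_id, de_adj_p, motif_adj_p,
#'   combined_rank`, ordered by rank.
#' @export
rank_candidates <- function(enrichment, de, side, adj_p_max = 0.05) {
  de_up <- significant_features(de, side = side, adj_p_max = adj_p_max)
  de_p <- stats::setNames(de_up$adj_p, de_up$feature_id)
  cand <- enrichment[enrichment$adj_p < adj_p_max &
                       enrichment$tf_gene_id %in% names(de_p), , drop = FALSE]
  dropped <- sum(enrichment$adj_p < adj_p_max) - nrow(cand)
  if (dropped > 0) {
    flc_log("rank_candidates: %d enriched motif(s) without an eligible TF",
            dropped)
  }
  if (nrow(cand) == 0) {
    return(data.frame(tf_gene_id = character(0), motif_id = character(0),
                      de_adj_p = numeric(0), motif_adj_p = numeric(0),
                      combined_rank = integer(0)))
  }
  ## one row per TF: best (smallest) motif adj_p when several motifs map
  cand <- cand[order(cand$adj_p, cand$motif_id), , drop = FALSE]
  cand <- cand[!duplicated(cand$tf_gene_id), , drop = FALSE]
  out <- data.frame(tf_gene_id = cand$tf_gene_id, motif_id = cand$motif_id,
                    de_adj_p = unname(de_p[cand$tf_gene_id]),
                    motif_adj_p = cand$adj_p, stringsAsFactors = FALSE)
  rs <- rank(out$motif_adj_p, ties.method = "average") +
    rank(out$de_adj_p, ties.method = "average")
  ord <- order(rs, out$motif_adj_p, out$tf_gene_id)
  out <- out[ord, , drop = FALSE]
  out$combined_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' TF ranking restricted to ChIP-bound DA peaks
#'
#' Re-runs the motif enrichment and combined ranking with the foreground
#' restricted to DA peaks that overlap a significant ChIP peak; the
#' background is the remaining DA peaks of the same side. An empty
#' restricted foreground yields an empty ranking (logged).
#'
#' @param da_peaks [interval_set()] of one side's significant DA peaks.
#' @param chip [interval_set()] of significant ChIP peaks.
#' @param sequences named peak sequences covering `da_peaks$name`.
#' @param motifs motif list.
#' @param de differential expression table for the contrast.
#' @param side cluster id whose upregulated TFs are eligible.
#' @param threshold_frac scan threshold, see [scan_motif()].
#' @param adj_p_max significance threshold.
#' @return as [rank_candidates()].
#' @export
rank_on_chip_subset <- function(da_peaks, chip, sequences, motifs, de, side,
                                threshold_frac = 0.8, adj_p_max = 0.05) {
  ov <- overlaps_any(da_peaks, chip)
  fg <- da_peaks$name[ov]
  bg <- da_peaks$name[!ov]
  if (length(fg) == 0) {
    flc_log("rank_on_chip_subset: no DA peaks overlap a ChIP peak")
    return(rank_candidates(
      enrich_motifs(character(0), character(0),
                    matrix(logical(0), 0, length(motifs),
                           dimnames = list(NULL,
                             vapply(motifs, `[[`, character(1), "motif_id"))),
                    motifs)[0, ], de, side, adj_p_max))
  }
  hits <- scan_motifs(sequences[c(fg, bg)], motifs, threshold_frac)
  if (length(bg) == 0) bg <- character(0)
  enr <- enrich_motifs(fg, bg, hits, motifs)
  rank_candidates(enr, de, side, adj_p_max)
}
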