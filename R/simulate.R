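#' Simulation design
#'
#' Parameters of the synthetic testis multiome. Defaults describe the
#' desk-scale study conditions used throughout the package: six clusters
#' (c0..c5) of 120 cells, with c0 playing the steroidogenic-progenitor role
#' and c3 the fetal-Leydig role; 300 genes and 400 accessibility peaks on
#' two 10 Mb chromosomes; 40 peaks more open in c0 and 70 in c3 (mirroring
#' the study's 386:684 imbalance of differentially accessible peaks); ChIP
#' peaks placed with the study's genomic-context mix (35/34/26/5%) and
#' covering 45% of c0-side and 5% of c3-side DA peaks (mirroring its
#' 43.7%/3.8% overlap); the progenitor's open-probability vector is an
#' epsilon-perturbation of the Leydig one on non-DA peaks so the pair is
#' mutually nearest in chromatin space while other clusters draw
#' independent accessibility profiles.
#'
#' @param n_cells_per_cluster named integer vector of cluster sizes.
#' @param n_genes,n_peaks feature counts.
#' @param genome_length_per_chrom named vector of chromosome lengths (bp).
#' @param rna_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param contrast length-2 character vector: the (progenitor, Leydig)
#'   cluster pair contrasted downstream.
#' @param n_da_up_a,n_da_up_b planted DA peaks per side.
#' @param da_rate_high,da_rate_low open probabilities of planted DA peaks
#'   in the favored / disfavored cluster.
#' @param similarity_epsilon s.d. of the perturbation tying the contrast
#'   pair's non-DA open probabilities together.
#' @param n_marker_genes,marker_fold cluster marker genes and their fold.
#' @param context_mix named fractions (promoter, gene_body, upstream,
#'   intergenic) for ChIP placement; must sum to 1.
#' @param n_chip_peaks context-placed ChIP peaks.
#' @param chip_overlap_frac named (a, b) fractions of each side's DA peaks
#'   to be covered by a ChIP peak.
#' @param motif_plant_rate fraction of foreground peaks receiving a motif.
#' @param qc_fail_rates named per-criterion failure fractions.
#' @param atac_peak_width width of simulated accessibility peaks (bp).
#' @param gc_content GC fraction of simulated peak sequences.
#' @param seed master seed; all generators are pure functions of
#'   (design, seed).
#' @return list of class `sim_design`.
#' @export
sim_design <- function(
    n_cells_per_cluster = stats::setNames(rep(120L, 6), paste0("c", 0:5)),
    n_genes = 300L,
    n_peaks = 400L,
    genome_length_per_chrom = c(chr1 = 1e7, chr2 = 1e7),
    rna_dispersion = 0.5,
    contrast = c(a = "c0", b = "c3"),
    n_da_up_a = 40L,
    n_da_up_b = 70L,
    da_rate_high = 0.65,
    da_rate_low = 0.25,
    similarity_epsilon = 0.05,
    n_marker_genes = 15L,
    marker_fold = 4,
    context_mix = c(promoter = 0.35, gene_body = 0.34,
                    upstream = 0.26, intergenic = 0.05),
    n_chip_peaks = 200L,
    chip_overlap_frac = c(a = 0.45, b = 0.05),
    motif_plant_rate = 0.6,
    qc_fail_rates = c(mito = 0.02, ribo = 0.01, hemo = 0.01, genes = 0.01,
                      frip = 0.02, frag_low = 0.01, frag_high = 0.005,
                      blacklist = 0.01),
    atac_peak_width = 500L,
    gc_content = 0.5,
    seed = 1L) {
  stopifnot(abs(sum(context_mix) - 1) < 1e-9,
            all(context_mix >= 0),
            all(c(da_rate_high, da_rate_low) >= 0),
            all(c(da_rate_high, da_rate_low) <= 1),
            all(qc_fail_rates >= 0 & qc_fail_rates <= 1),
            all(contrast %in% names(n_cells_per_cluster)))
  structure(as.list(environment()), class = c("sim_design", "list"))
}

## Run `expr` under a deterministic RNG stream derived from (seed, offset),
## restoring the caller's stream afterwards: generators stay pure.
with_sim_seed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
  expr
}

## Gene territories: one gene per `spacing` bp window so that promoter
## (-1 kb) and upstream (-10 kb) windows of different genes never collide
## and the intended gene is always the nearest TSS for placements within
## its territory.
layout_genes <- function(design) {
  per_chrom <- largest_remainder(design$genome_length_per_chrom, design$n_genes)
  chroms <- names(design$genome_length_per_chrom)
  recs <- list()
  idx <- 1L
  for (ci in seq_along(chroms)) {
    n <- per_chrom[ci]
    if (n == 0) next
    spacing <- floor(design$genome_length_per_chrom[ci] / n)
    if (spacing < 25000) {
      stop("genome too small for ", n, " gene territories on ", chroms[ci],
           "; increase genome_length_per_chrom")
    }
    body_len <- pmin(8000L, floor(spacing * 0.2)) -
      sample(0:3000, n, replace = TRUE)
    body_len <- pmax(body_len, 2000L)
    start <- (seq_len(n) - 1L) * spacing + floor(spacing * 0.4)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    recs[[ci]] <- data.frame(
      chrom = chroms[ci], start = start, end = start + body_len,
      strand = strand,
      gene_id = sprintf("gene_%03d", idx:(idx + n - 1L)),
      stringsAsFactors = FALSE
    )
    idx <- idx + n
  }
  df <- do.call(rbind, recs)
  gene_models(df$chrom, df$start, df$end, df$strand, df$gene_id)
}

## Evenly spaced accessibility peaks, kept >= 1 kb apart so a 300 bp ChIP
## peak centered inside one ATAC peak can never touch another.
layout_peaks <- function(design) {
  per_chrom <- largest_remainder(design$genome_length_per_chrom, design$n_peaks)
  chroms <- names(design$genome_length_per_chrom)
  recs <- list()
  for (ci in seq_along(chroms)) {
    n <- per_chrom[ci]
    if (n == 0) next
    spacing <- floor(design$genome_length_per_chrom[ci] / n)
    if (spacing < design$atac_peak_width + 1000) {
      stop("genome too small for ", n, " peaks on ", chroms[ci])
    }
    s <- (seq_len(n) - 1L) * spacing + floor(spacing / 2)
    recs[[ci]] <- data.frame(chrom = chroms[ci], start = s,
                             end = s + design$atac_peak_width)
  }
  df <- do.call(rbind, recs)
  interval_set(df$chrom, df$start, df$end,
               sprintf("peak_%03d", seq_len(nrow(df))))
}

#' Simulate the single-nucleus multiome
#'
#' Generates, as a pure function of the design and its seed: a gene-by-cell
#' negative-binomial RNA count matrix with cluster-specific marker genes; a
#' binarized peak-by-cell accessibility matrix whose per-peak open
#' probability is cluster-specific and modulated by each cell's fragment
#' depth; a per-cell QC table whose metrics are drawn from scaled Beta
#' distributions with failures planted by explicit override (so the failing
#' set is exact, not a tail event); the peak and gene geography; and ground
#' truth tables (planted DA peaks, marker/DE genes, QC failures) that the
#' pipeline never reads.
#'
#' @param design a [sim_design()].
#' @return list: `rna`, `atac` (sparse matrices), `cells` (QC/cluster
#'   table), `peaks` ([interval_set()]), `genes` ([gene_models()]), and
#'   `truth` (list of `qc_fail`, `da`, `markers`, `open_prob`).
#' @export
simulate_multiome <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  with_sim_seed(design$seed, 0L, {
    K <- length(design$n_cells_per_cluster)
    clusters <- names(design$n_cells_per_cluster)
    labels <- rep(clusters, design$n_cells_per_cluster)
    n_cells <- length(labels)
    cell_id <- sprintf("cell_%04d", seq_len(n_cells))
    genes <- layout_genes(design)
    peaks <- layout_peaks(design)
    n_genes <- nrow(genes)
    n_peaks <- nrow(peaks)
    a <- design$contrast[["a"]]; b <- design$contrast[["b"]]

    ## --- ATAC open probabilities ---------------------------------------
    base_b <- stats::runif(n_peaks, 0.05, 0.35)
    open_prob <- matrix(NA_real_, n_peaks, K, dimnames = list(peaks$name, clusters))
    for (k in clusters) {
      if (k == b) {
        open_prob[, k] <- base_b
      } else if (k == a) {
        open_prob[, k] <- pmin(pmax(
          base_b + stats::rnorm(n_peaks, 0, design$similarity_epsilon),
          0.01), 0.99)
      } else {
        open_prob[, k] <- stats::runif(n_peaks, 0.1, 0.9)
      }
    }
    da_idx <- sample.int(n_peaks, design$n_da_up_a + design$n_da_up_b)
    up_a <- da_idx[seq_len(design$n_da_up_a)]
    up_b <- da_idx[design$n_da_up_a + seq_len(design$n_da_up_b)]
    open_prob[up_a, a] <- design$da_rate_high
    open_prob[up_a, b] <- design$da_rate_low
    open_prob[up_b, b] <- design$da_rate_high
    open_prob[up_b, a] <- design$da_rate_low
    n_da <- length(up_a) + length(up_b)
    da_truth <- data.frame(
      peak_id = peaks$name[c(up_a, up_b)],
      up_in = rep(c(a, b), c(length(up_a), length(up_b))),
      rate_high = rep(design$da_rate_high, n_da),
      rate_low = rep(design$da_rate_low, n_da),
      stringsAsFactors = FALSE
    )

    ## --- QC metrics with planted failures ------------------------------
    cells <- data.frame(
      cell_id = cell_id, cluster_label = labels,
      pct_mito = pmin(0.10 * stats::rbeta(n_cells, 2, 8), 0.095),
      pct_ribo = pmin(0.10 * stats::rbeta(n_cells, 2, 8), 0.095),
      pct_hemo = pmin(0.005 * stats::rbeta(n_cells, 2, 8), 0.0045),
      n_genes_detected = as.integer(round(stats::runif(n_cells, 800, 6000))),
      frip = pmax(pmin(0.2 + 0.6 * stats::rbeta(n_cells, 2, 2), 0.95), 0.21),
      n_frag_in_peaks = as.integer(pmin(pmax(round(
        exp(stats::rnorm(n_cells, log(5000), 0.4))), 300L), 20000L)),
      pct_blacklist = pmin(0.05 * stats::rbeta(n_cells, 2, 8), 0.045),
      stringsAsFactors = FALSE
    )
    fail_n <- round(design$qc_fail_rates * n_cells)
    total_fail <- sum(fail_n)
    if (total_fail > n_cells) stop("qc_fail_rates plant more failures than cells")
    fail_cells <- sample.int(n_cells, total_fail)
    crit <- rep(names(fail_n), fail_n)
    for (i in seq_along(fail_cells)) {
      j <- fail_cells[i]
      switch(crit[i],
        mito = { cells$pct_mito[j] <- stats::runif(1, 0.10, 0.5) },
        ribo = { cells$pct_ribo[j] <- stats::runif(1, 0.10, 0.5) },
        hemo = { cells$pct_hemo[j] <- stats::runif(1, 0.005, 0.05) },
        genes = { cells$n_genes_detected[j] <- sample(0:500, 1) },
        frip = { cells$frip[j] <- stats::runif(1, 0, 0.20) },
        frag_low = { cells$n_frag_in_peaks[j] <- sample(1:250, 1) },
        frag_high = { cells$n_frag_in_peaks[j] <- sample(25000:60000, 1) },
        blacklist = { cells$pct_blacklist[j] <- stats::runif(1, 0.05, 0.3) }
      )
    }
    qc_fail <- data.frame(cell_id = cell_id[fail_cells], criterion = crit,
                          stringsAsFactors = FALSE)

    ## --- ATAC matrix: Bernoulli openness modulated by fragment depth ---
    depth_factor <- cells$n_frag_in_peaks / stats::median(cells$n_frag_in_peaks)
    kidx <- match(labels, clusters)
    p_cell <- open_prob[, kidx, drop = FALSE]
    ## smooth depth modulation keeps probabilities in [0,1]
    p_eff <- 1 - (1 - p_cell)^rep(depth_factor, each = n_peaks)
    atac <- Matrix::Matrix(
      matrix(stats::rbinom(n_peaks * n_cells, 1, as.vector(p_eff)),
             n_peaks, n_cells, dimnames = list(peaks$name, cell_id)),
      sparse = TRUE
    )

    ## --- RNA matrix: cluster-specific negative binomial ----------------
    base_mu <- stats::rgamma(n_genes, shape = 2, scale = 1) + 0.1
    expr_mat <- matrix(base_mu, n_genes, K, dimnames = list(genes$gene_id, clusters))
    marker_idx <- seq_len(min(K * design$n_marker_genes, n_genes))
    marker_cluster <- rep(clusters, each = design$n_marker_genes)[seq_along(marker_idx)]
    for (i in seq_along(marker_idx)) {
      expr_mat[marker_idx[i], marker_cluster[i]] <-
        expr_mat[marker_idx[i], marker_cluster[i]] * design$marker_fold
    }
    markers <- data.frame(gene_id = genes$gene_id[marker_idx],
                          cluster = marker_cluster, stringsAsFactors = FALSE)
    sf <- exp(stats::rnorm(n_cells, 0, 0.3))
    mu <- expr_mat[, kidx, drop = FALSE] * rep(sf, each = n_genes)
    rna <- Matrix::Matrix(
      matrix(stats::rnbinom(n_genes * n_cells, mu = as.vector(mu),
                            size = 1 / design$rna_dispersion),
             n_genes, n_cells, dimnames = list(genes$gene_id, cell_id)),
      sparse = TRUE
    )

    list(rna = rna, atac = atac, cells = cells, peaks = peaks, genes = genes,
         truth = list(qc_fail = qc_fail, da = da_truth, markers = markers,
                      open_prob = open_prob))
  })
}

## Geometric placement of one ChIP midpoint of a given context class
## relative to a gene; guarantees the recovered class by construction
## (territory spacing makes the intended gene the nearest TSS).
place_midpoint <- function(class, gene, t) {
  tss <- gene$tss
  plus <- gene$strand == "+"
  switch(class,
    promoter = {
      d <- -sample(0:t$promoter_upstream, 1)
      if (plus) tss + d else tss - d
    },
    gene_body = {
      if (plus) sample((gene$start + 1L):(gene$end - 1L), 1)
      else sample(gene$start:(gene$end - 2L), 1)
    },
    upstream = {
      d <- -sample((t$promoter_upstream + 1L):t$upstream_window, 1)
      if (plus) tss + d else tss - d
    },
    stop("place_midpoint handles promoter/gene_body/upstream only")
  )
}

#' Simulate ChIP peaks with controlled genomic context and DA overlap
#'
#' Places `n_chip_peaks` 300 bp peaks whose true context composition equals
#' `context_mix` exactly (largest-remainder apportionment), each positioned
#' relative to a sampled gene so that its class is unambiguous by
#' construction. Context-placed peaks are rejected if they would touch any
#' supplied accessibility peak, so the designed DA overlap is controlled
#' exclusively by the second stage: for each contrast side, a
#' `chip_overlap_frac` fraction of the true DA peaks receives a ChIP peak
#' centered on its midpoint (truth rows carry `source = "da_overlap"` and
#' no context class).
#'
#' @param design a [sim_design()].
#' @param genes a [gene_models()] table.
#' @param da_truth the `truth$da` table from [simulate_multiome()]
#'   (optional; `NULL` skips overlap planting).
#' @param atac_peaks the accessibility [interval_set()] to avoid
#'   (optional).
#' @param t thresholds (peak width and context windows).
#' @return list: `peaks` ([interval_set()]) and `truth` (data.frame
#'   `name, context, source, gene_id, da_peak`).
#' @export
simulate_chip_peaks <- function(design, genes, da_truth = NULL,
                                atac_peaks = NULL, t = flc_thresholds()) {
  stopifnot(inherits(design, "sim_design"), inherits(genes, "gene_models"))
  with_sim_seed(design$seed, 1L, {
    w <- t$chip_peak_width
    half <- w %/% 2L
    classes <- c("promoter", "gene_body", "upstream", "intergenic")
    counts <- largest_remainder(design$context_mix[classes], design$n_chip_peaks)
    mids <- integer(0); chs <- character(0)
    cls <- character(0); gid <- character(0)
    avoid <- atac_peaks
    genome_len <- design$genome_length_per_chrom
    for (ci in seq_along(classes)) {
      k <- classes[ci]
      for (r in seq_len(counts[ci])) {
        ok <- FALSE
        for (try in 1:200) {
          if (k == "intergenic") {
            ch <- sample(names(genome_len), 1)
            mid <- sample.int(genome_len[[ch]] - 2L * half, 1) + half
            g_ch <- genes[genes$chrom == ch, , drop = FALSE]
            ## strictly farther than the upstream window from every TSS and
            ## outside every gene body -> classifier must say intergenic
            if (nrow(g_ch) > 0 &&
                (min(abs(mid - g_ch$tss)) <= t$upstream_window ||
                 any(mid >= g_ch$start & mid < g_ch$end))) next
            gi <- NA_character_
          } else {
            j <- sample.int(nrow(genes), 1)
            mid <- place_midpoint(k, genes[j, ], t)
            ch <- genes$chrom[j]
            if (mid < half || mid > genome_len[[ch]] - half) next
            gi <- genes$gene_id[j]
          }
          cand <- interval_set(ch, mid - half, mid + (w - half), "cand")
          if (!is.null(avoid) && nrow(avoid) > 0 && overlaps_any(cand, avoid)) next
          ok <- TRUE
          break
        }
        if (!ok) {
          stop("could not place a ", k, " ChIP peak; ",
               "increase genome_length_per_chrom")
        }
        mids <- c(mids, mid); chs <- c(chs, ch)
        cls <- c(cls, k); gid <- c(gid, gi)
      }
    }
    truth <- data.frame(name = sprintf("chip_ctx_%03d", seq_along(mids)),
                        context = cls, source = "context", gene_id = gid,
                        da_peak = NA_character_, stringsAsFactors = FALSE)
    chip <- data.frame(chrom = chs, start = mids - half,
                       end = mids + (w - half), name = truth$name,
                       stringsAsFactors = FALSE)

    ## stage 2: cover the designed fraction of each side's DA peaks
    if (!is.null(da_truth) && nrow(da_truth) > 0 && !is.null(atac_peaks)) {
      sides <- c(a = design$contrast[["a"]], b = design$contrast[["b"]])
      for (s in names(sides)) {
        frac <- design$chip_overlap_frac[[s]]
        ids <- da_truth$peak_id[da_truth$up_in == sides[[s]]]
        n_cover <- round(frac * length(ids))
        if (n_cover == 0) next
        chosen <- ids[sample.int(length(ids), n_cover)]
        pk <- atac_peaks[match(chosen, atac_peaks$name), , drop = FALSE]
        mid <- (pk$start + pk$end) %/% 2L
        nm <- sprintf("chip_da_%s_%03d", s, seq_len(n_cover))
        chip <- rbind(chip, data.frame(chrom = pk$chrom, start = mid - half,
                                       end = mid + (w - half), name = nm,
                                       stringsAsFactors = FALSE))
        truth <- rbind(truth, data.frame(name = nm, context = NA_character_,
                                         source = "da_overlap",
                                         gene_id = NA_character_,
                                         da_peak = chosen,
                                         stringsAsFactors = FALSE))
      }
    }
    peaks <- interval_set(chip$chrom, chip$start, chip$end, chip$name)
    list(peaks = peaks, truth = truth)
  })
}

#' Simulate near-deterministic motif models
#'
#' PFMs with one dominant base per column (probability `sharpness`), each
#' mapped to a supplied TF gene id; consensi are drawn to be distinct.
#'
#' @param tf_gene_ids one TF gene per motif.
#' @param length motif length (bp).
#' @param sharpness probability of the dominant base per column.
#' @param seed RNG seed.
#' @return named list of [flc_motif()] objects (`motif_01`, ...).
#' @export
simulate_motifs <- function(tf_gene_ids, length = 8L, sharpness = 0.85,
                            seed = 1L) {
  with_sim_seed(seed, 2L, {
    bases <- c("A", "C", "G", "T")
    seen <- character(0)
    out <- list()
    for (i in seq_along(tf_gene_ids)) {
      repeat {
        cons <- sample(bases, length, replace = TRUE)
        key <- paste(cons, collapse = "")
        if (!key %in% seen) break
      }
      seen <- c(seen, key)
      pfm <- matrix((1 - sharpness) / 3, 4, length,
                    dimnames = list(bases, NULL))
      pfm[cbind(match(cons, bases), seq_len(length))] <- sharpness
      id <- sprintf("motif_%02d", i)
      out[[id]] <- flc_motif(id, tf_gene_ids[i], round(pfm * 100))
    }
    out
  })
}

#' Simulate peak sequences with planted motif occurrences
#'
#' Random sequences at the designed GC content; peaks listed in `plant`
#' receive the motif consensus (or its reverse complement for `-` strand)
#' at a recorded offset. Offsets/strands are drawn when not supplied.
#'
#' @param peaks an [interval_set()]; sequence length = interval width.
#' @param motifs named list of [flc_motif()] objects.
#' @param plant data.frame `peak, motif_id` with optional `offset`
#'   (0-based) and `strand` columns; `NULL` plants nothing.
#' @param gc GC fraction of the background sequence.
#' @param seed RNG seed.
#' @return list: `sequences` (named character) and `plant` (realized truth
#'   with offsets and strands).
#' @export
simulate_peak_sequences <- function(peaks, motifs, plant = NULL, gc = 0.5,
                                    seed = 1L) {
  stopifnot(inherits(peaks, "interval_set"))
  with_sim_seed(seed, 3L, {
    widths <- peaks$end - peaks$start
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(widths, function(wd) {
      paste(sample(names(probs), wd, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    names(seqs) <- peaks$name
    realized <- NULL
    if (!is.null(plant) && nrow(plant) > 0) {
      realized <- plant
      if (is.null(realized$strand)) {
        realized$strand <- sample(c("+", "-"), nrow(realized), replace = TRUE)
      }
      if (is.null(realized$offset)) realized$offset <- NA_integer_
      for (i in seq_len(nrow(realized))) {
        pk <- realized$peak[i]
        if (!pk %in% names(seqs)) stop("unknown peak in plant table: ", pk)
        cons <- motif_consensus(motifs[[realized$motif_id[i]]])
        L <- nchar(cons)
        wd <- nchar(seqs[[pk]])
        if (L > wd) {
          stop("motif consensus (", L, " bp) longer than peak ", pk,
               " (", wd, " bp)")
        }
        off <- realized$offset[i]
        if (is.na(off)) off <- sample(0:(wd - L), 1)
        ins <- if (realized$strand[i] == "-") revcomp(cons) else cons
        substr(seqs[[pk]], off + 1L, off + L) <- ins
        realized$offset[i] <- off
      }
    }
    list(sequences = seqs,
         plant = realized %||% data.frame(peak = character(0),
                                          motif_id = character(0),
                                          offset = integer(0),
                                          strand = character(0)))
  })
}

#' Simulate a bulk differential-expression table
#'
#' Stand-in for an externally fitted knockout-vs-control DE table (the
#' pipeline consumes such a table, it never fits the model). Planted up-
#' and down-regulated genes get near-zero p-values and log2 fold changes of
#' `+/-lfc`; all other genes draw p from Uniform(0.05, 1) so that, after BH
#' adjustment, exactly the planted genes are significant at adj p < 0.05.
#'
#' @param gene_ids full gene universe of the table.
#' @param up_ids,down_ids planted significant genes (disjoint).
#' @param lfc absolute log2 fold change of planted genes.
#' @param seed RNG seed.
#' @return differential table (`feature_id, group_a, group_b, effect, p,
#'   adj_p, direction`) with `group_a = "KO"`, `group_b = "WT"`;
#'   `up_in_a` marks genes up in the knockout.
#' @export
simulate_bulk_de <- function(gene_ids, up_ids, down_ids, lfc = 2, seed = 1L) {
  stopifnot(!anyDuplicated(gene_ids), all(c(up_ids, down_ids) %in% gene_ids),
            length(intersect(up_ids, down_ids)) == 0)
  with_sim_seed(seed, 4L, {
    n <- length(gene_ids)
    p <- stats::runif(n, 0.05, 1)
    eff <- stats::rnorm(n, 0, 0.2)
    up <- gene_ids %in% up_ids
    dn <- gene_ids %in% down_ids
    p[up | dn] <- stats::runif(sum(up | dn), 1e-12, 1e-8)
    eff[up] <- abs(stats::rnorm(sum(up), lfc, 0.2))
    eff[dn] <- -abs(stats::rnorm(sum(dn), lfc, 0.2))
    new_differential_table(gene_ids, "KO", "WT", eff, p)
  })
}

#' Simulate a blacklist interval set
#'
#' A handful of fixed-width artifact regions placed clear of the supplied
#' peak set (so default pipelines are blacklist-clean) unless
#' `overlap_peaks` asks that some planted regions cover peaks.
#'
#' @param design a [sim_design()].
#' @param peaks [interval_set()] to avoid (or cover).
#' @param n number of blacklist regions.
#' @param overlap_peaks how many regions should cover a peak.
#' @return an [interval_set()].
#' @export
simulate_blacklist <- function(design, peaks, n = 10L, overlap_peaks = 0L) {
  with_sim_seed(design$seed, 5L, {
    wd <- 1000L
    recs <- list()
    i <- 0L
    while (i < n - overlap_peaks) {
      ch <- sample(names(design$genome_length_per_chrom), 1)
      s <- sample.int(design$genome_length_per_chrom[[ch]] - wd, 1) - 1L
      cand <- interval_set(ch, s, s + wd, "bl")
      if (nrow(peaks) > 0 && overlaps_any(cand, peaks)) next
      i <- i + 1L
      recs[[i]] <- data.frame(chrom = ch, start = s, end = s + wd)
    }
    if (overlap_peaks > 0) {
      pk <- peaks[sample.int(nrow(peaks), overlap_peaks), , drop = FALSE]
      mid <- (pk$start + pk$end) %/% 2L
      recs <- c(recs, list(data.frame(chrom = pk$chrom, start = mid - wd %/% 2L,
                                      end = mid + wd %/% 2L)))
    }
    df <- do.call(rbind, recs)
    interval_set(df$chrom, df$start, df$end,
                 sprintf("blacklist_%02d", seq_len(nrow(df))))
  })
}
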