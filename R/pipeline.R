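#' Write a JASPAR PFM file
#'
#' Bracketed JASPAR dialect, one block per motif; the TF gene id is stored
#' as the second header token.
#'
#' @param motifs named list of [flc_motif()] objects.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_jaspar <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(sprintf(">%s %s", m$motif_id, m$tf_gene_id), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(m$pfm[b, ], trim = TRUE), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read / write peak sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path FASTA location.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

## ---- pipeline stages ------------------------------------------------------
## Each stage reads its inputs from `outdir` (written by earlier stages) and
## writes TSV/BED/FASTA outputs back, so `all` is just the chain. File names
## are the stage contract and are stable across runs.

sim_paths <- function(outdir) {
  file.path(outdir, c(
    rna_mtx = "rna_counts.mtx", rna_features = "rna_features.tsv",
    rna_barcodes = "rna_barcodes.tsv",
    atac_mtx = "atac_counts.mtx", atac_features = "atac_features.tsv",
    atac_barcodes = "atac_barcodes.tsv",
    cells = "cells.tsv", peaks = "atac_peaks.bed", genes = "gene_models.tsv",
    chip = "chip_peaks.bed", blacklist = "blacklist.bed",
    fasta = "peak_sequences.fa", jaspar = "motifs.jaspar",
    bulk = "bulk_de.tsv"
  )) |> stats::setNames(c("rna_mtx", "rna_features", "rna_barcodes",
                          "atac_mtx", "atac_features", "atac_barcodes",
                          "cells", "peaks", "genes", "chip", "blacklist",
                          "fasta", "jaspar", "bulk"))
}

need_file <- function(path, stage) {
  if (!file.exists(path)) {
    stop("stage '", stage, "' needs missing input: ", path, call. = FALSE)
  }
  path
}

#' Generate and write the full synthetic dataset
#'
#' Runs every generator of the synthetic module under the design derived
#' from `config` and writes the complete input bundle (matrices, cell
#' table, BED/TSV geography, FASTA sequences, JASPAR motifs, bulk DE
#' table) plus ground-truth tables under `truth/`.
#'
#' @param config an [flc_config()]; its seed drives every generator.
#' @param outdir output directory (created if absent).
#' @param design optional [sim_design()] override (its seed is replaced by
#'   the config seed).
#' @return invisibly, the simulation bundle.
#' @export
stage_simulate <- function(config, outdir, design = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  design <- design %||% sim_design(seed = config$seed)
  design$seed <- config$seed
  sim <- simulate_multiome(design)
  chip <- simulate_chip_peaks(design, sim$genes, sim$truth$da, sim$peaks)
  blacklist <- simulate_blacklist(design, rbind(sim$peaks, chip$peaks))
  a <- design$contrast[["a"]]; b <- design$contrast[["b"]]
  markers <- sim$truth$markers
  tf_ids <- c(markers$gene_id[markers$cluster == a][1:3],
              markers$gene_id[markers$cluster == b][1:2],
              markers$gene_id[!markers$cluster %in% c(a, b)][1:3])
  motifs <- simulate_motifs(tf_ids, seed = design$seed)
  ## plant side-a motifs in side-a DA peaks, side-b motifs in side-b peaks
  da <- sim$truth$da
  plant <- with_sim_seed(design$seed, 6L, {
    covered <- chip$truth$da_peak[chip$truth$source == "da_overlap"]
    mk_plant <- function(side, motif_ids) {
      ids <- da$peak_id[da$up_in == side]
      n <- round(design$motif_plant_rate * length(ids))
      ## ChIP-covered DA peaks are planted first: co-regulator motifs
      ## concentrate where the factor binds, which is what the restricted
      ## (ChIP-subset) ranking is designed to detect
      pri <- intersect(ids, covered)
      rest <- setdiff(ids, pri)
      chosen <- c(pri[seq_len(min(n, length(pri)))],
                  rest[sample.int(length(rest), max(0, n - length(pri)))])
      ## every motif of the side's TFs occurs in each of its planted peaks
      expand.grid(peak = chosen, motif_id = motif_ids,
                  stringsAsFactors = FALSE)
    }
    rbind(mk_plant(a, names(motifs)[1:3]), mk_plant(b, names(motifs)[4:5]))
  })
  seqs <- simulate_peak_sequences(sim$peaks, motifs, plant,
                                  gc = design$gc_content, seed = design$seed)
  down_clusters <- c(a, setdiff(names(design$n_cells_per_cluster), c(a, b))[1])
  up_clusters <- setdiff(names(design$n_cells_per_cluster),
                         c(a, b, down_clusters))[1]
  bulk <- simulate_bulk_de(
    sim$genes$gene_id,
    up_ids = markers$gene_id[markers$cluster %in% up_clusters],
    down_ids = markers$gene_id[markers$cluster %in% down_clusters],
    seed = design$seed
  )

  p <- sim_paths(outdir)
  write_matrix(sim$rna, p["rna_mtx"], p["rna_features"], p["rna_barcodes"])
  write_matrix(sim$atac, p["atac_mtx"], p["atac_features"], p["atac_barcodes"])
  write_tsv_file(sim$cells, p["cells"])
  write_intervals(sim$peaks, p["peaks"])
  write_gene_models(sim$genes, p["genes"])
  write_intervals(chip$peaks, p["chip"])
  write_intervals(blacklist, p["blacklist"])
  write_fasta(seqs$sequences, p["fasta"])
  write_jaspar(motifs, p["jaspar"])
  write_tsv_file(bulk, p["bulk"])
  tdir <- file.path(outdir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  write_tsv_file(sim$truth$qc_fail, file.path(tdir, "qc_fail.tsv"))
  write_tsv_file(sim$truth$da, file.path(tdir, "da_peaks.tsv"))
  write_tsv_file(sim$truth$markers, file.path(tdir, "markers.tsv"))
  write_tsv_file(chip$truth, file.path(tdir, "chip_placement.tsv"))
  write_tsv_file(seqs$plant, file.path(tdir, "motif_plant.tsv"))
  flc_log("simulate: wrote synthetic bundle to %s (config %s, seed %d)",
          outdir, config_digest(config), config$seed)
  invisible(list(sim = sim, chip = chip, blacklist = blacklist,
                 motifs = motifs, sequences = seqs, bulk = bulk,
                 design = design))
}

load_bundle <- function(outdir, stage) {
  p <- sim_paths(outdir)
  for (f in p) need_file(f, stage)
  list(
    rna = read_matrix(p["rna_mtx"], p["rna_features"], p["rna_barcodes"]),
    atac = read_matrix(p["atac_mtx"], p["atac_features"], p["atac_barcodes"]),
    cells = read_tsv_file(p["cells"]),
    peaks = read_intervals(p["peaks"]),
    genes = read_gene_models(p["genes"]),
    chip = read_intervals(p["chip"]),
    blacklist = read_intervals(p["blacklist"]),
    sequences = read_fasta(p["fasta"]),
    motifs = read_jaspar(p["jaspar"]),
    bulk = read_tsv_file(p["bulk"])
  )
}

retained_cells <- function(config, outdir, stage) {
  f <- file.path(outdir, "retained_cells.tsv")
  if (file.exists(f)) return(read_tsv_file(f))
  cells <- read_tsv_file(need_file(file.path(outdir, "cells.tsv"), stage))
  joint_filter(cells, config$thresholds)
}

#' Individual pipeline stages
#'
#' Each stage reads the outputs of earlier stages from `outdir` and writes
#' its own TSV outputs there; see [run_cli()] for the chained `all` run.
#'
#' @param config an [flc_config()].
#' @param outdir working directory shared by the stages.
#' @param cluster_a,cluster_b the contrasted cluster ids.
#' @return invisibly, the stage's main result.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
stage_qc <- function(config, outdir) {
  cells <- read_tsv_file(need_file(file.path(outdir, "cells.tsv"), "qc"))
  kept <- joint_filter(cells, config$thresholds)
  write_tsv_file(kept, file.path(outdir, "retained_cells.tsv"))
  write_tsv_file(attr(kept, "qc_report"), file.path(outdir, "qc_report.tsv"))
  invisible(kept)
}

#' @rdname pipeline-stages
#' @export
stage_similarity <- function(config, outdir, cluster_b = "c3") {
  b <- load_bundle(outdir, "similarity")
  cells <- retained_cells(config, outdir, "similarity")
  atac <- b$atac[, cells$cell_id, drop = FALSE]
  t <- config$thresholds
  sel <- select_variable_peaks(atac, min(t$n_variable_peaks, nrow(atac)),
                               depth = cells$n_frag_in_peaks)
  d <- cluster_distances(atac, cells$cluster_label, sel,
                         depth = cells$n_frag_in_peaks,
                         min_cells = t$min_cluster_cells)
  write_tsv_file(data.frame(cluster = rownames(d), as.data.frame(d),
                            check.names = FALSE),
                 file.path(outdir, "cluster_distances.tsv"))
  writeLines(dendrogram_newick(build_dendrogram(d)),
             file.path(outdir, "cluster_dendrogram.nwk"))
  nn <- nearest_cluster(d, cluster_b)
  write_tsv_file(data.frame(target = cluster_b, nearest = nn$cluster,
                            distance = nn$distance),
                 file.path(outdir, "nearest_cluster.tsv"))
  invisible(list(distances = d, nearest = nn))
}

#' @rdname pipeline-stages
#' @export
stage_diff <- function(config, outdir, cluster_a = "c0", cluster_b = "c3") {
  b <- load_bundle(outdir, "diff")
  cells <- retained_cells(config, outdir, "diff")
  t <- config$thresholds
  rna <- b$rna[, cells$cell_id, drop = FALSE]
  atac <- b$atac[, cells$cell_id, drop = FALSE]
  de <- de_test(rna, cells$cluster_label, cluster_a, cluster_b, t)
  da <- da_test(atac, cells$cluster_label, cluster_a, cluster_b,
                covariate = cells$n_frag_in_peaks, t = t)
  write_tsv_file(de, file.path(outdir, "de_genes.tsv"))
  write_tsv_file(da, file.path(outdir, "da_peaks.tsv"))
  for (side in c(cluster_a, cluster_b)) {
    ids <- significant_features(da, side, t$adj_p_max)$feature_id
    sub <- b$peaks[b$peaks$name %in% ids, , drop = FALSE]
    class(sub) <- c("interval_set", "data.frame")
    write_intervals(sub, file.path(outdir, paste0("da_peaks_", side, ".bed")))
  }
  invisible(list(de = de, da = da))
}

#' @rdname pipeline-stages
#' @export
stage_annotate <- function(config, outdir) {
  b <- load_bundle(outdir, "annotate")
  t <- config$thresholds
  chip <- resize_peaks(b$chip, t$chip_peak_width)
  chip <- filter_peaks(chip, b$blacklist, config$genome)
  ann <- classify_context(chip, b$genes, t)
  write_tsv_file(ann, file.path(outdir, "chip_annotated.tsv"))
  comp <- context_composition(ann)
  write_tsv_file(data.frame(context = names(comp), percent = unname(comp)),
                 file.path(outdir, "chip_context_composition.tsv"))
  invisible(ann)
}

#' @rdname pipeline-stages
#' @export
stage_integrate <- function(config, outdir, cluster_a = "c0", cluster_b = "c3") {
  b <- load_bundle(outdir, "integrate")
  cells <- retained_cells(config, outdir, "integrate")
  t <- config$thresholds
  da <- read_tsv_file(need_file(file.path(outdir, "da_peaks.tsv"), "integrate"))
  de <- read_tsv_file(need_file(file.path(outdir, "de_genes.tsv"), "integrate"))
  ann <- read_tsv_file(need_file(file.path(outdir, "chip_annotated.tsv"),
                                 "integrate"))
  chip <- interval_set(ann$chrom, ann$start, ann$end, ann$name)
  da_sub <- function(side) {
    ids <- significant_features(da, side, t$adj_p_max)$feature_id
    out <- b$peaks[b$peaks$name %in% ids, , drop = FALSE]
    class(out) <- c("interval_set", "data.frame")
    out
  }
  ov <- rbind(overlap_fraction(da_sub(cluster_a), chip, cluster_a),
              overlap_fraction(da_sub(cluster_b), chip, cluster_b))
  write_tsv_file(ov, file.path(outdir, "chip_da_overlap.tsv"))
  targets <- assign_targets(ann)
  write_tsv_file(data.frame(gene_id = targets$targets),
                 file.path(outdir, "chip_targets.tsv"))
  venn <- intersect_deg_targets(
    targets$targets,
    significant_features(de, cluster_a, t$adj_p_max)$feature_id,
    significant_features(de, cluster_b, t$adj_p_max)$feature_id
  )
  write_tsv_file(data.frame(region = names(venn$regions),
                            n = unname(venn$regions)),
                 file.path(outdir, "target_deg_venn.tsv"))
  rna <- b$rna[, cells$cell_id, drop = FALSE]
  atac <- b$atac[, cells$cell_id, drop = FALSE]
  links <- link_peaks(atac, rna, b$peaks, b$genes,
                      depth = cells$n_frag_in_peaks,
                      adj_p_max = t$adj_p_max)
  write_tsv_file(links, file.path(outdir, "peak_gene_links.tsv"))
  lf <- rbind(
    linked_fraction(da_sub(cluster_a)$name, links, cluster_a),
    linked_fraction(da_sub(cluster_b)$name, links, cluster_b)
  )
  write_tsv_file(lf, file.path(outdir, "da_linked_fraction.tsv"))
  invisible(list(overlap = ov, venn = venn, links = links, linked = lf))
}

#' @rdname pipeline-stages
#' @export
stage_motifs <- function(config, outdir, cluster_a = "c0", cluster_b = "c3") {
  b <- load_bundle(outdir, "motifs")
  t <- config$thresholds
  da <- read_tsv_file(need_file(file.path(outdir, "da_peaks.tsv"), "motifs"))
  de <- read_tsv_file(need_file(file.path(outdir, "de_genes.tsv"), "motifs"))
  hits <- scan_motifs(b$sequences, b$motifs)
  out <- list()
  for (side in c(cluster_a, cluster_b)) {
    fg <- significant_features(da, side, t$adj_p_max)$feature_id
    if (length(fg) == 0) next
    pool <- setdiff(rownames(hits), fg)
    bg <- with_sim_seed(config$seed, 7L,
                        gc_matched_background(fg, pool, b$sequences))
    enr <- enrich_motifs(fg, bg, hits, b$motifs)
    write_tsv_file(enr, file.path(outdir, paste0("motif_enrichment_", side,
                                                 ".tsv")))
    rk <- rank_candidates(enr, de, side, t$adj_p_max)
    write_tsv_file(rk, file.path(outdir, paste0("tf_candidates_", side,
                                                ".tsv")))
    out[[side]] <- list(enrichment = enr, ranking = rk)
  }
  ## restricted run: side-a DA peaks that carry a ChIP peak
  ann <- read_tsv_file(need_file(file.path(outdir, "chip_annotated.tsv"),
                                 "motifs"))
  chip <- interval_set(ann$chrom, ann$start, ann$end, ann$name)
  ids <- significant_features(da, cluster_a, t$adj_p_max)$feature_id
  da_a <- b$peaks[b$peaks$name %in% ids, , drop = FALSE]
  class(da_a) <- c("interval_set", "data.frame")
  rk_chip <- rank_on_chip_subset(da_a, chip, b$sequences, b$motifs, de,
                                 cluster_a, adj_p_max = t$adj_p_max)
  write_tsv_file(rk_chip, file.path(outdir, "tf_candidates_chip_subset.tsv"))
  out$chip_subset <- rk_chip
  invisible(out)
}

#' @rdname pipeline-stages
#' @export
stage_project <- function(config, outdir) {
  b <- load_bundle(outdir, "project")
  cells <- retained_cells(config, outdir, "project")
  t <- config$thresholds
  rna <- b$rna[, cells$cell_id, drop = FALSE]
  res <- project(b$bulk, rna, cells$cluster_label, t)
  for (dir in names(res)) {
    r <- res[[dir]]
    write_tsv_file(data.frame(gene_id = rownames(r$z), as.data.frame(r$z),
                              check.names = FALSE),
                   file.path(outdir, paste0("projection_z_", dir, ".tsv")))
    write_tsv_file(data.frame(gene_id = names(r$groups),
                              group = unname(r$groups),
                              k_selected = r$k_selected),
                   file.path(outdir, paste0("projection_groups_", dir, ".tsv")))
    write_tsv_file(r$affected,
                   file.path(outdir, paste0("projection_affected_", dir,
                                            ".tsv")))
    write_tsv_file(data.frame(gene_id = rownames(r$heatmap),
                              as.data.frame(r$heatmap), check.names = FALSE),
                   file.path(outdir, paste0("projection_heatmap_", dir,
                                            ".tsv")))
  }
  invisible(res)
}
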