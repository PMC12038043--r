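## Shared desk-scale fixtures built in code. Tests stay quiet.
options(flcpipe.verbose = FALSE)

## Small simulation design used where full defaults would be slow.
small_design <- function(seed = 11L, ...) {
  args <- list(
    n_cells_per_cluster = stats::setNames(rep(40L, 4), paste0("c", 0:3)),
    n_genes = 60L,
    n_peaks = 100L,
    genome_length_per_chrom = c(chr1 = 6e6, chr2 = 6e6),
    n_da_up_a = 6L,
    n_da_up_b = 10L,
    n_marker_genes = 5L,
    n_chip_peaks = 100L,
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_design, args)
}

## Cell table in which every cell passes every QC gate.
passing_cells <- function(n, prefix = "cell") {
  data.frame(
    cell_id = sprintf("%s_%03d", prefix, seq_len(n)),
    cluster_label = "c0",
    pct_mito = 0.02, pct_ribo = 0.02, pct_hemo = 0.001,
    n_genes_detected = 2000L,
    frip = 0.5, n_frag_in_peaks = 5000L, pct_blacklist = 0.01,
    stringsAsFactors = FALSE
  )
}

## Upper-tail hypergeometric by direct choose() arithmetic: the independent
## oracle for enrich_motifs (never calls phyper).
hyper_upper_oracle <- function(fw, W, N, nf) {
  support <- max(0, W - (N - nf)):min(nf, W)
  js <- support[support >= fw]
  if (!length(js)) return(0)
  sum(choose(W, js) * choose(N - W, nf - js)) / choose(N, nf)
}
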