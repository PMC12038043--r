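#' Analysis thresholds
#'
#' All numeric gates used across the pipeline, with defaults equal to the
#' values stated for the original study: RNA cells require <10% mitochondrial,
#' <10% ribosomal and <0.5% hemoglobin content and >500 detected genes; ATAC
#' cells require >20% of reads in peaks, >250 but <25,000 fragments in peaks
#' and <5% of fragments in blacklist regions. Chromatin similarity uses the
#' 2000 most variable peaks; ChIP peaks are resized to 300 bp; the promoter
#' window is -1 kb of the TSS and the upstream window -10 kb to -1 kb;
#' differential calls use BH-adjusted p < 0.05; the projection calls a cluster
#' affected when more than 20% of the genes have z > 1, groups genes with a
#' 2%-minimum-size dendrogram cut, and ignores clusters with fewer than
#' `min_cluster_cells` cells (the study dropped a 2-cell cluster).
#'
#' @param ... named overrides of any listed field.
#' @return a validated list of class `flc_thresholds`.
#' @export
#' @examples
#' t <- flc_thresholds()
#' t$rna_mito_max
#' flc_thresholds(n_variable_peaks = 100)$n_variable_peaks
flc_thresholds <- function(...) {
  t <- list(
    rna_mito_max = 0.10,
    rna_ribo_max = 0.10,
    rna_hemo_max = 0.005,
    rna_min_genes = 500L,
    atac_frip_min = 0.20,
    atac_frag_min = 250L,
    atac_frag_max = 25000L,
    atac_blacklist_max = 0.05,
    n_variable_peaks = 2000L,
    chip_peak_width = 300L,
    promoter_upstream = 1000L,
    upstream_window = 10000L,
    adj_p_max = 0.05,
    chip_fdr_max = 1e-5,
    projection_z_cut = 1.0,
    projection_deg_frac = 0.20,
    projection_min_group_frac = 0.02,
    min_cluster_cells = 3L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(t))
  if (length(bad)) stop("unknown threshold field(s): ", paste(bad, collapse = ", "))
  t[names(dots)] <- dots
  validate_thresholds(t)
  structure(t, class = c("flc_thresholds", "list"))
}

validate_thresholds <- function(t) {
  fr <- c("rna_mito_max", "rna_ribo_max", "rna_hemo_max", "atac_frip_min",
          "atac_blacklist_max", "adj_p_max", "chip_fdr_max",
          "projection_deg_frac", "projection_min_group_frac")
  for (f in fr) {
    if (t[[f]] < 0 || t[[f]] > 1) stop("threshold ", f, " must lie in [0,1]")
  }
  ct <- c("rna_min_genes", "atac_frag_min", "atac_frag_max",
          "n_variable_peaks", "chip_peak_width", "promoter_upstream",
          "upstream_window", "min_cluster_cells")
  for (f in ct) {
    if (t[[f]] <= 0) stop("threshold ", f, " must be positive")
  }
  if (t$atac_frag_min >= t$atac_frag_max)
    stop("atac_frag_min must be < atac_frag_max")
  if (t$promoter_upstream >= t$upstream_window)
    stop("promoter_upstream must be < upstream_window")
  invisible(t)
}

#' Canonical mouse chromosome names
#'
#' chr1-19, chrX and chrY; peaks on any other sequence are dropped at read
#' time, matching the canonical-chromosome filter of the original analysis.
#'
#' @return character vector of 21 chromosome names.
#' @export
canonical_chromosomes <- function() {
  paste0("chr", c(1:19, "X", "Y"))
}

#' Run configuration
#'
#' Bundles thresholds, the master seed, file locations and the allowed
#' chromosome set. Every stochastic stage derives its RNG stream from the
#' seed stored here, so any stage re-run with the same configuration is
#' reproducible bit for bit.
#'
#' @param thresholds an [flc_thresholds()] object.
#' @param seed integer master seed.
#' @param paths named list of input/output locations (free-form).
#' @param genome character vector of allowed chromosome names.
#' @return list of class `flc_config`.
#' @export
flc_config <- function(thresholds = flc_thresholds(), seed = 1L,
                       paths = list(), genome = canonical_chromosomes()) {
  stopifnot(inherits(thresholds, "flc_thresholds"),
            is.numeric(seed), length(seed) == 1)
  structure(list(thresholds = thresholds, seed = as.integer(seed),
                 paths = paths, genome = genome),
            class = c("flc_config", "list"))
}

#' Read / write a run configuration
#'
#' The on-disk form is a flat `key: value` YAML document; any thresholds
#' field may be overridden, everything else falls back to the study
#' defaults.
#'
#' @param path file location.
#' @param config an `flc_config` object (for writing).
#' @return `read_config()` returns an `flc_config`; `write_config()` the path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  tnames <- names(flc_thresholds())
  tover <- y[intersect(names(y), tnames)]
  flc_config(
    thresholds = do.call(flc_thresholds, tover),
    seed = y$seed %||% 1L,
    paths = y$paths %||% list(),
    genome = y$genome %||% canonical_chromosomes()
  )
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "flc_config"))
  flat <- c(unclass(config$thresholds),
            list(seed = config$seed, genome = config$genome,
                 paths = config$paths))
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Short digest of a configuration
#'
#' Stable hash of the configuration content, recorded in run logs so a
#' re-run can be matched to the exact settings that produced an output.
#'
#' @param config an `flc_config`.
#' @return 8-hex-digit character scalar.
#' @export
config_digest <- function(config) {
  fnv1a(paste(deparse(unclass(config)), collapse = ""))
}
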