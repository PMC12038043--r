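test_that("target assignment unions nearest genes, with a promoter-only variant", {
  ann <- data.frame(
    name = paste0("p", 1:4),
    nearest_gene = c("GeneA", "GeneA", "GeneA", "GeneB"),
    context = c("promoter", "gene_body", "promoter", "upstream"),
    stringsAsFactors = FALSE
  )
  tg <- assign_targets(ann)
  expect_equal(tg$targets, c("GeneA", "GeneB"))
  expect_equal(nrow(tg$mapping), 4)
  expect_equal(assign_targets(ann, promoter_only = TRUE)$targets, "GeneA")
  expect_equal(assign_targets(ann[0, ])$targets, character(0))
})

test_that("Venn regions match a membership-vector oracle", {
  v <- intersect_deg_targets(paste0("t", 1:2), paste0("a", 1:3), paste0("b", 1:4))
  expect_equal(unname(v$regions), c(2, 3, 4, 0, 0, 0, 0))
  expect_equal(unname(v$coverage), c(0, 0))

  ## targets cover all of deg_a -> 100% coverage
  v2 <- intersect_deg_targets(c("x", "y", "z"), c("x", "y"), "q")
  expect_equal(unname(v2$coverage["deg_a"]), 1)

  set.seed(15)
  univ <- sprintf("g%03d", 1:200)
  tg <- sample(univ, 80); da <- sample(univ, 60); db <- sample(univ, 90)
  v3 <- intersect_deg_targets(tg, da, db)
  mem <- cbind(t = univ %in% tg, a = univ %in% da, b = univ %in% db)
  mem <- mem[rowSums(mem) > 0, ]
  expect_equal(sum(v3$regions), nrow(mem))
  expect_equal(unname(v3$regions["all_three"]),
               sum(mem[, 1] & mem[, 2] & mem[, 3]))
  expect_equal(unname(v3$regions["targets_deg_a"]),
               sum(mem[, 1] & mem[, 2] & !mem[, 3]))
  expect_equal(unname(v3$coverage["deg_b"]), sum(db %in% tg) / 90)
})

test_that("overlap fractions reproduce the printed-count arithmetic under truncation", {
  ## arithmetic identities on the study's printed numerator/denominator pairs
  expect_equal(percent_trunc(169, 386), 43.7)
  expect_equal(percent_trunc(26, 684), 3.8)
  set.seed(16)
  s <- seq(0, by = 1000, length.out = 386)
  da <- interval_set("chr1", s, s + 500)
  chip_on <- sample(386, 169)
  chip <- interval_set("chr1", s[chip_on] + 100, s[chip_on] + 400)
  rep <- overlap_fraction(da, chip, "c0")
  expect_equal(rep$n_overlapping, 169)
  expect_equal(rep$percent, 43.7)
  expect_equal(overlap_fraction(da, interval_set("chr2", 1, 2), "x")$percent, 0)
  expect_true(is.na(overlap_fraction(da[0, ], chip, "x")$percent))
})

test_that("peak-gene linkage finds planted couplings and controls the null", {
  set.seed(17)
  n <- 400
  cells <- sprintf("cell%03d", 1:n)
  genes <- gene_models("chr1", c(1000, 300000), c(6000, 305000), c("+", "+"),
                       c("gLinked", "gNull"))
  peaks <- interval_set("chr1", c(500, 299000), c(1000, 299500),
                        c("pLinked", "pNull"))
  acc_linked <- rbinom(n, 1, 0.5)
  atac <- Matrix::Matrix(rbind(pLinked = acc_linked,
                               pNull = rbinom(n, 1, 0.5)), sparse = TRUE)
  colnames(atac) <- cells
  ## expression of gLinked proportional to accessibility of pLinked
  rna <- Matrix::Matrix(rbind(gLinked = acc_linked * 20 + 1,
                              gNull = rpois(n, 5)), sparse = TRUE)
  colnames(rna) <- cells
  links <- link_peaks(atac, rna, peaks, genes, depth = rep(1000, n))
  row <- links[links$peak_id == "pLinked" & links$gene_id == "gLinked", ]
  expect_true(row$linked)
  expect_gt(row$correlation, 0.8)
  nullrow <- links[links$peak_id == "pNull" & links$gene_id == "gNull", ]
  expect_false(nullrow$linked)

  ## negating expression flips the correlation sign
  rna_neg <- rna
  rna_neg["gLinked", ] <- max(rna["gLinked", ]) - rna["gLinked", ] + 1
  links_neg <- link_peaks(atac, rna_neg, peaks, genes, depth = rep(1000, n))
  expect_lt(links_neg$correlation[links_neg$peak_id == "pLinked" &
                                    links_neg$gene_id == "gLinked"], -0.8)

  ## cell-permutation invariance
  perm <- sample(n)
  links_p <- link_peaks(atac[, perm], rna[, perm], peaks, genes,
                        depth = rep(1000, n))
  expect_equal(links_p$correlation[order(links_p$peak_id, links_p$gene_id)],
               links$correlation[order(links$peak_id, links$gene_id)],
               tolerance = 1e-12)

  ## p-values match the reference correlation test on the same normalized
  ## vectors (constant depth leaves accessibility on the 0/1 scale)
  expr_norm <- as.matrix(lognormalize(rna))["gNull", ]
  ct <- cor.test(as.numeric(atac["pNull", ]), expr_norm)
  expect_equal(nullrow$p, ct$p.value, tolerance = 1e-9)
  expect_equal(nullrow$correlation, unname(ct$estimate), tolerance = 1e-9)
})

test_that("linkage respects the search window and skips degenerate features", {
  n <- 50
  cells <- sprintf("c%02d", 1:n)
  genes <- gene_models("chr1", 1000, 2000, "+", "gA")
  peaks <- interval_set("chr1", c(1500, 900000), c(2000, 900500),
                        c("near", "far"))
  set.seed(18)
  atac <- Matrix::Matrix(rbind(near = rbinom(n, 1, 0.5),
                               far = rbinom(n, 1, 0.5)), sparse = TRUE)
  colnames(atac) <- cells
  rna <- Matrix::Matrix(rbind(gA = rpois(n, 5) + 1, filler = rpois(n, 8) + 1),
                        sparse = TRUE)
  colnames(rna) <- cells
  links <- link_peaks(atac, rna, peaks, genes, depth = rep(100, n),
                      window = 10000)
  expect_equal(links$peak_id, "near")

  atac["near", ] <- 1  # zero variance -> pair skipped
  expect_equal(nrow(link_peaks(atac, rna, peaks, genes, depth = rep(100, n),
                               window = 10000)), 0)
})

test_that("linked fractions reproduce the printed pairs and saturate at 100", {
  links <- data.frame(peak_id = sprintf("p%03d", 1:188),
                      linked = TRUE, stringsAsFactors = FALSE)
  expect_equal(linked_fraction(sprintf("p%03d", 1:386), links)$percent, 48.7)
  links2 <- data.frame(peak_id = sprintf("q%03d", 1:328), linked = TRUE)
  ## truncation, not rounding: 328/684 = 47.953...% prints as 47.9
  expect_equal(linked_fraction(sprintf("q%03d", 1:684), links2)$percent, 47.9)
  expect_equal(linked_fraction("p001", links)$percent, 100)
})

test_that("designed ChIP coverage of planted DA peaks is recovered exactly", {
  design <- small_design(seed = 51L,
                         chip_overlap_frac = c(a = 0.5, b = 0),
                         n_chip_peaks = 40L)
  sim <- simulate_multiome(design)
  chip <- simulate_chip_peaks(design, sim$genes, sim$truth$da, sim$peaks)
  da_a <- sim$peaks[sim$peaks$name %in%
                      sim$truth$da$peak_id[sim$truth$da$up_in == "c0"], ]
  class(da_a) <- c("interval_set", "data.frame")
  da_b <- sim$peaks[sim$peaks$name %in%
                      sim$truth$da$peak_id[sim$truth$da$up_in == "c3"], ]
  class(da_b) <- c("interval_set", "data.frame")
  expect_equal(overlap_fraction(da_a, chip$peaks)$percent, 50)
  ## zero designed coverage means zero overlap on the other side
  expect_equal(overlap_fraction(da_b, chip$peaks)$n_overlapping, 0)

  ## full coverage saturates at 100.0
  design2 <- small_design(seed = 52L, chip_overlap_frac = c(a = 1, b = 0),
                          n_chip_peaks = 20L)
  sim2 <- simulate_multiome(design2)
  chip2 <- simulate_chip_peaks(design2, sim2$genes, sim2$truth$da, sim2$peaks)
  da2 <- sim2$peaks[sim2$peaks$name %in%
                      sim2$truth$da$peak_id[sim2$truth$da$up_in == "c0"], ]
  class(da2) <- c("interval_set", "data.frame")
  expect_equal(overlap_fraction(da2, chip2$peaks)$percent, 100)
})
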