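demo_motif <- function(cons = "TGACCT", id = "m1", tf = "TF1", sharp = 0.9) {
  bases <- c("A", "C", "G", "T")
  pfm <- matrix((1 - sharp) / 3 * 100, 4, nchar(cons),
                dimnames = list(bases, NULL))
  idx <- match(strsplit(cons, NULL)[[1]], bases)
  pfm[cbind(idx, seq_along(idx))] <- sharp * 100
  flc_motif(id, tf, pfm)
}

test_that("JASPAR reader handles bracketed and plain dialects and round-trips", {
  f <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA0001.1 TFA",
    "A [ 10 0 80 5 ]", "C [ 10 0 10 5 ]", "G [ 70 0  5 5 ]",
    "T [ 10 100 5 85 ]",
    ">MA0002.1 TFB",
    "A 1 2 3 4", "C 1 2 3 4", "G 1 2 3 4", "T 97 94 91 88"
  ), f)
  ms <- read_jaspar(f)
  expect_named(ms, c("MA0001.1", "MA0002.1"))
  expect_equal(ms[["MA0001.1"]]$tf_gene_id, "TFA")
  expect_equal(unname(ms[["MA0001.1"]]$pfm["G", 1]), 70)
  expect_equal(motif_consensus(ms[["MA0002.1"]]), "TTTT")
  expect_equal(motif_consensus(ms[["MA0001.1"]]), "GTAT")
  lo <- motif_logodds(ms[["MA0001.1"]])
  expect_equal(dim(lo), c(4L, 4L))

  f2 <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(ms, f2)
  back <- read_jaspar(f2)
  expect_equal(back[["MA0002.1"]]$pfm, ms[["MA0002.1"]]$pfm, ignore_attr = TRUE)
})

test_that("motif scanning finds planted consensus on both strands", {
  m <- demo_motif("TGACCT")
  base <- paste(rep("A", 40), collapse = "")
  planted <- paste0(substr(base, 1, 10), "TGACCT", substr(base, 17, 40))
  rc_planted <- paste0(substr(base, 1, 10), "AGGTCA", substr(base, 17, 40))
  seqs <- c(fwd = planted, rev = rc_planted, none = base)
  sc <- scan_motif(seqs, m)
  expect_equal(unname(sc$hits), c(TRUE, TRUE, FALSE))
  expect_equal(sc$sites$offset[sc$sites$seq_id == "fwd"], 10)
  expect_equal(sc$sites$strand[sc$sites$seq_id == "fwd"], "+")
  expect_equal(sc$sites$offset[sc$sites$seq_id == "rev"], 10)
  expect_equal(sc$sites$strand[sc$sites$seq_id == "rev"], "-")
})

test_that("scan hits equal an exhaustive window-scoring oracle on random sequences", {
  set.seed(19)
  m <- demo_motif("ACGTAC", sharp = 0.7)
  lo <- motif_logodds(m)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(1:200, function(i) {
    paste(sample(bases, 50, TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("s%03d", 1:200)
  sc <- scan_motif(seqs, m, threshold_frac = 0.8)
  cut <- 0.8 * sum(apply(lo, 2, max))
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, NULL)[[1]]), collapse = ""))
  oracle <- vapply(seqs, function(s) {
    any(vapply(seq_len(nchar(s) - 5), function(o) {
      fw <- sum(lo[cbind(match(strsplit(substr(s, o, o + 5), NULL)[[1]], bases),
                         1:6)])
      rv <- sum(lo[cbind(match(strsplit(rc(substr(s, o, o + 5)), NULL)[[1]],
                               bases), 1:6)])
      fw >= cut || rv >= cut
    }, logical(1)))
  }, logical(1))
  expect_equal(unname(sc$hits), unname(oracle))
  ## sequences shorter than the motif yield no hit
  expect_false(any(scan_motif(c(tiny = "ACG"), m)$hits))
})

test_that("enrichment p-values are exact hypergeometric upper tails", {
  mk_hits <- function(fw, nf, bw, nb) {
    ids <- c(sprintf("f%02d", seq_len(nf)), sprintf("b%02d", seq_len(nb)))
    h <- matrix(c(seq_len(nf) <= fw, seq_len(nb) <= bw), ncol = 1,
                dimnames = list(ids, "m1"))
    list(fg = ids[seq_len(nf)], bg = ids[nf + seq_len(nb)], hits = h)
  }
  ## all-success tail: fg 10/10 with motif, bg 0/100 -> 1 / C(110,10)
  x <- mk_hits(10, 10, 0, 100)
  e <- enrich_motifs(x$fg, x$bg, x$hits)
  expect_equal(e$p, 1 / choose(110, 10), tolerance = 1e-12)
  expect_true(is.infinite(e$fold_enrichment))

  ## identical with-motif fractions: fold 1, p >= 0.5
  x <- mk_hits(5, 10, 50, 100)
  e <- enrich_motifs(x$fg, x$bg, x$hits)
  expect_equal(e$fold_enrichment, 1)
  expect_gte(e$p, 0.5)

  ## enumeration oracle on a specific table
  x <- mk_hits(8, 10, 20, 100)
  e <- enrich_motifs(x$fg, x$bg, x$hits)
  expect_equal(e$p, hyper_upper_oracle(8, 28, 110, 10), tolerance = 1e-12)

  expect_error(enrich_motifs(c("a", "b"), c("b", "c"), x$hits), "disjoint")
})

test_that("GC-matched background reproduces the foreground GC histogram", {
  set.seed(20)
  n <- 300
  gc <- runif(n, 0.2, 0.8)
  seqs <- vapply(gc, function(g) {
    paste(sample(c("A", "C", "G", "T"), 100, TRUE,
                 prob = c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)),
          collapse = "")
  }, character(1))
  names(seqs) <- sprintf("p%03d", 1:n)
  fg <- names(seqs)[1:60]
  pool <- names(seqs)[61:300]
  bg <- gc_matched_background(fg, pool, seqs)
  expect_equal(length(bg), 60)
  expect_true(all(bg %in% pool))
  bins <- function(ids) table(floor(gc_content(seqs[ids]) / 0.05))
  expect_equal(bins(bg), bins(fg))
})

test_that("candidate ranking combines the two criteria as a rank-sum", {
  enr <- data.frame(
    motif_id = sprintf("m%02d", 1:10),
    tf_gene_id = sprintf("tf%02d", 1:10),
    adj_p = c(0.001, 0.002, 0.004, 0.008, 0.01, 0.02, 0.03, 0.04, 0.045, 0.2),
    stringsAsFactors = FALSE
  )
  de <- data.frame(
    feature_id = sprintf("tf%02d", 1:10),
    group_a = "c0", group_b = "c3",
    effect = rep(1, 10), p = rep(1e-4, 10),
    adj_p = c(0.04, 0.001, 0.03, 0.002, 0.01, 0.005, 0.02, 0.008, 0.045, 0.001),
    direction = "up_in_a", stringsAsFactors = FALSE
  )
  rk <- rank_candidates(enr, de, "c0")
  expect_equal(nrow(rk), 9) # tf10 fails the motif criterion
  ## brute-force rank-sum oracle
  el <- merge(enr[enr$adj_p < 0.05, c("tf_gene_id", "adj_p")],
              de[de$adj_p < 0.05, c("feature_id", "adj_p")],
              by.x = "tf_gene_id", by.y = "feature_id")
  rs <- rank(el$adj_p.x) + rank(el$adj_p.y)
  oracle <- el$tf_gene_id[order(rs, el$adj_p.x, el$tf_gene_id)]
  expect_equal(rk$tf_gene_id, oracle)
  expect_equal(rk$combined_rank, seq_len(9))

  ## dominance: best on both criteria ranks first regardless of others
  expect_equal(rk$tf_gene_id[1], "tf02")
  ## single eligible TF gets rank 1
  rk1 <- rank_candidates(enr[2, ], de, "c0")
  expect_equal(rk1$combined_rank, 1L)

  ## ranking depends only on the order of the p-value columns (the ^1.5
  ## transform is monotone and preserves the 0.05 eligibility split here)
  enr2 <- enr
  enr2$adj_p <- enr$adj_p^1.5
  de2 <- de
  de2$adj_p <- de$adj_p^1.5
  expect_equal(rank_candidates(enr2, de2, "c0")$tf_gene_id, rk$tf_gene_id)
})

test_that("ChIP-restricted ranking boosts motifs confined to ChIP-bound peaks", {
  set.seed(22)
  n <- 60
  s <- seq(0, by = 2000, length.out = n)
  da <- interval_set("chr1", s, s + 500, sprintf("p%02d", 1:n))
  ## ChIP covers the first 20 DA peaks
  chip <- interval_set("chr1", s[1:20] + 100, s[1:20] + 400)
  m_chip <- demo_motif("TTGACCTA", "m_chip", "tfChip")
  m_base <- demo_motif("CCGGAATT", "m_base", "tfBase")
  motifs <- list(m_chip = m_chip, m_base = m_base)
  bg_seq <- function() paste(sample(c("A", "C", "G", "T"), 120, TRUE),
                             collapse = "")
  seqs <- vapply(1:n, function(i) bg_seq(), character(1))
  names(seqs) <- da$name
  ## plant the ChIP motif only in ChIP-overlapped peaks, the base motif everywhere
  for (i in 1:16) substr(seqs[i], 20, 27) <- "TTGACCTA"
  for (i in seq(1, n, 3)) substr(seqs[i], 60, 67) <- "CCGGAATT"
  de <- data.frame(feature_id = c("tfChip", "tfBase"), group_a = "c0",
                   group_b = "c3", effect = 1, p = 1e-6,
                   adj_p = c(1e-4, 1e-4), direction = "up_in_a",
                   stringsAsFactors = FALSE)
  rk_restricted <- rank_on_chip_subset(da, chip, seqs, motifs, de, "c0")
  expect_true("tfChip" %in% rk_restricted$tf_gene_id)
  expect_equal(rk_restricted$tf_gene_id[1], "tfChip")

  ## empty overlap yields an empty ranking
  chip_far <- interval_set("chr2", 1, 300)
  expect_equal(nrow(rank_on_chip_subset(da, chip_far, seqs, motifs, de, "c0")),
               0)
})
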