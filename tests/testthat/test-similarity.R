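make_atac <- function(nr, nc, seed = 1) {
  set.seed(seed)
  m <- Matrix::Matrix(matrix(rbinom(nr * nc, 1, 0.4), nr, nc), sparse = TRUE)
  dimnames(m) <- list(sprintf("p%03d", seq_len(nr)), sprintf("c%03d", seq_len(nc)))
  m
}

test_that("variable-peak selection matches a brute-force variance ranking", {
  m <- make_atac(50, 40, seed = 2)
  depth <- rep(1, 40)
  sel <- select_variable_peaks(m, 10, depth)
  v <- apply(as.matrix(normalize_depth(m, depth)), 1, var)
  oracle <- rownames(m)[order(-v, rownames(m))][1:10]
  expect_identical(sel, oracle)

  ## a constant peak is never selected while any varying peak exists
  m2 <- m
  m2[1, ] <- 1
  expect_false("p001" %in% select_variable_peaks(m2, 49, depth))
  ## n = total peaks returns the identity set
  expect_setequal(select_variable_peaks(m, 50, depth), rownames(m))
  expect_setequal(suppressMessages(select_variable_peaks(m, 80, depth)),
                  rownames(m))
})

test_that("cluster distances are Euclidean on per-cluster mean profiles", {
  ## hand case: mean vectors (1,0) vs (0,1) at unit depth -> sqrt(2)
  m <- Matrix::Matrix(cbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)), sparse = TRUE)
  dimnames(m) <- list(c("p1", "p2"), paste0("cell", 1:4))
  labels <- c("A", "A", "B", "B")
  d <- cluster_distances(m, labels, depth = rep(1, 4), min_cells = 2L)
  expect_equal(d["A", "B"], sqrt(2), tolerance = 1e-12)
  expect_equal(diag(d), c(A = 0, B = 0))

  ## identical mean vectors -> zero distance
  m2 <- Matrix::Matrix(cbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1)), sparse = TRUE)
  dimnames(m2) <- dimnames(m)
  d2 <- cluster_distances(m2, labels, depth = rep(1, 4), min_cells = 2L)
  expect_equal(d2["A", "B"], 0)
})

test_that("distance matrix equals a naive double-loop oracle and is permutation invariant", {
  m <- make_atac(30, 80, seed = 3)
  labels <- rep(c("c0", "c1", "c2", "c3"), each = 20)
  depth <- sample(1000:5000, 80)
  d <- cluster_distances(m, labels, depth = depth)
  norm <- as.matrix(normalize_depth(m, depth))
  oracle <- matrix(0, 4, 4, dimnames = list(paste0("c", 0:3), paste0("c", 0:3)))
  for (a in rownames(oracle)) for (b in rownames(oracle)) {
    ma <- rowMeans(norm[, labels == a, drop = FALSE])
    mb <- rowMeans(norm[, labels == b, drop = FALSE])
    oracle[a, b] <- sqrt(sum((ma - mb)^2))
  }
  expect_equal(unclass(d), oracle, tolerance = 1e-12, ignore_attr = TRUE)

  perm <- sample(80)
  dp <- cluster_distances(m[, perm], labels[perm], depth = depth[perm])
  expect_equal(unclass(dp), unclass(d), tolerance = 1e-9, ignore_attr = TRUE)

  ## homogeneity: scaling all signals by c scales every distance by c
  d3 <- cluster_distances(m * 3, labels, depth = depth)
  expect_equal(d3[, ], d[, ] * 3, tolerance = 1e-9)
})

## Independent agglomeration oracle: complete linkage by direct set merging.
complete_linkage_oracle <- function(d) {
  groups <- as.list(rownames(d))
  merges <- list()
  while (length(groups) > 1) {
    best <- c(NA, NA); h <- Inf
    for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
      hij <- max(d[groups[[i]], groups[[j]]])
      if (hij < h) { h <- hij; best <- c(j, i) }
    }
    merges[[length(merges) + 1]] <-
      list(members = sort(c(groups[[best[1]]], groups[[best[2]]])), height = h)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  merges
}

test_that("dendrogram construction matches brute-force complete-linkage agglomeration", {
  ## 2 clusters: single merge at their distance
  d2 <- matrix(c(0, 1.5, 1.5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  h2 <- build_dendrogram(d2)
  expect_equal(h2$height, 1.5)
  expect_error(build_dendrogram(d2[1, 1, drop = FALSE]), ">= 2 clusters")

  ## 3 clusters with d = {AB:1, AC:5, BC:5}: (A,B) at 1 then +C at 5
  d3 <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h3 <- build_dendrogram(d3)
  expect_equal(h3$height, c(1, 5))
  expect_setequal(h3$labels[-h3$merge[1, ]], c("A", "B"))

  ## 6-cluster random fixture vs the oracle's merge heights and member sets
  set.seed(8)
  x <- matrix(rnorm(6 * 4), 6, dimnames = list(paste0("k", 1:6), NULL))
  d6 <- as.matrix(dist(x))
  h6 <- build_dendrogram(d6)
  oracle <- complete_linkage_oracle(d6)
  expect_equal(h6$height, vapply(oracle, `[[`, numeric(1), "height"),
               tolerance = 1e-12)
  ## members of each hclust merge step match the oracle's
  members_of <- function(h, step) {
    idx <- function(s) {
      row <- h$merge[s, ]
      unlist(lapply(row, function(v) if (v < 0) h$labels[-v] else idx(v)))
    }
    sort(idx(step))
  }
  for (s in seq_along(oracle)) {
    expect_equal(members_of(h6, s), oracle[[s]]$members)
  }
  expect_true(!is.unsorted(h6$height))
  expect_match(dendrogram_newick(h6), "^\\(.*\\);$")
})

test_that("nearest-cluster query is the argmin with deterministic tie-break", {
  d <- matrix(0, 4, 4, dimnames = list(c("c0", "c1", "c3", "c5"),
                                       c("c0", "c1", "c3", "c5")))
  d["c3", c("c0", "c1", "c5")] <- c(2.1, 4.0, 4.4)
  d[, "c3"] <- d["c3", ]
  nn <- nearest_cluster(d, "c3")
  expect_equal(nn$cluster, "c0")
  expect_equal(nn$distance, 2.1)
  expect_error(nearest_cluster(d, "c9"), "not in distance matrix")

  dt <- matrix(1, 3, 3, dimnames = list(c("b", "a", "c"), c("b", "a", "c")))
  diag(dt) <- 0
  expect_equal(nearest_cluster(dt, "b")$cluster, "a") # ties: first id in order
})

test_that("a planted epsilon-perturbed progenitor is recovered as the nearest cluster", {
  design <- small_design(seed = 21L)
  sim <- simulate_multiome(design)
  kept <- joint_filter(sim$cells)
  atac <- sim$atac[, kept$cell_id]
  d <- cluster_distances(atac, kept$cluster_label,
                         depth = kept$n_frag_in_peaks)
  expect_equal(nearest_cluster(d, design$contrast[["b"]])$cluster,
               design$contrast[["a"]])
  expect_equal(nearest_cluster(d, design$contrast[["a"]])$cluster,
               design$contrast[["b"]])
})
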