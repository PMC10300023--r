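test_that("median-of-ratios size factors match hand computation and DESeq2", {
  m <- cbind(s1 = c(10L, 20L, 40L), s2 = c(20L, 40L, 80L))
  rownames(m) <- c("a", "b", "c")
  norm <- median_ratio_normalize(m)
  expect_equal(norm$size_factors[["s2"]] / norm$size_factors[["s1"]], 2)
  expect_equal(norm$normalized[, 1], norm$normalized[, 2])
  expect_equal(unname(norm$size_factors), unname(size_factors_brute(m)))

  ident <- cbind(s1 = c(5L, 9L, 3L), s2 = c(5L, 9L, 3L))
  rownames(ident) <- letters[1:3]
  expect_equal(unname(median_ratio_normalize(ident)$size_factors), c(1, 1))

  set.seed(42)
  big <- matrix(rnbinom(606, mu = 50, size = 2) + 1L, 101, 6,
                dimnames = list(sprintf("g%d", 1:101), sprintf("s%d", 1:6)))
  expect_equal(unname(median_ratio_normalize(big)$size_factors),
               unname(size_factors_brute(big)))
  if (requireNamespace("DESeq2", quietly = TRUE)) {
    expect_equal(unname(median_ratio_normalize(big)$size_factors),
                 unname(DESeq2::estimateSizeFactorsForMatrix(big)),
                 tolerance = 1e-8)
  }
})

test_that("all-zero genes are excluded from size factors but kept in the matrix", {
  m <- rbind(a = c(10L, 20L), b = c(30L, 60L), z = c(0L, 0L))
  colnames(m) <- c("s1", "s2")
  norm <- median_ratio_normalize(m)
  m2 <- m[c("a", "b"), ]
  expect_equal(norm$size_factors, median_ratio_normalize(m2)$size_factors)
  expect_true("z" %in% rownames(norm$normalized))
  zero <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(median_ratio_normalize(zero), "no gene")
})

test_that("variable-gene filter applies mean and n-1 variance thresholds on log2", {
  l2 <- rbind(
    const = rep(3, 4),                    # variance 0 -> out
    lowmean = c(0.5, 1.5, 0.5, 1.5),      # mean 1 < 2 -> out
    lowvar = c(3, 4, 3, 4),               # var 1/3... below 5 -> out
    keep = c(0.5, 3, 6, 9))               # mean 4.625, var ~13.6 -> in
  colnames(l2) <- sprintf("s%d", 1:4)
  expect_equal(filter_variable_genes(l2), "keep")
  expect_equal(var(l2["keep", ]), 13.5625, tolerance = 1e-9)
  # boundary: variance exactly at the threshold is excluded (strict >)
  edge <- rbind(e = c(1, 3, 5))
  colnames(edge) <- sprintf("s%d", 1:3)
  expect_equal(var(edge["e", ]), 4)
  expect_length(filter_variable_genes(edge, mean_min = 0, var_min = 4), 0)
  expect_equal(filter_variable_genes(edge, mean_min = 0, var_min = 3.99), "e")
})

test_that("Spearman distance is zero for duplicated or monotone-transformed profiles", {
  set.seed(1)
  m <- matrix(rlnorm(200, 3, 1), 50, 4,
              dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:4)))
  m[, 2] <- m[, 1]                 # duplicate
  m[, 3] <- m[, 1]^2 + 5           # strictly monotone transform
  cl <- cluster_samples(log2(m + 1), k = 2)
  expect_equal(cl$distance["s1", "s2"], 0)
  expect_equal(cl$distance["s1", "s3"], 0, tolerance = 1e-12)
  expect_equal(cl$labels[["s1"]], cl$labels[["s2"]])
  # duplicates merge first
  expect_equal(min(cl$merge_heights), 0)
})

test_that("constant sample profiles are rejected", {
  m <- matrix(rlnorm(60), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  m[, 2] <- 7
  expect_error(cluster_samples(m), "constant.*b")
})

test_that("planted clusters are recovered with auto k", {
  sim <- simulate_expression(1000, c(8, 8, 8, 8), 50, lfc = 3, seed = 7)
  norm <- median_ratio_normalize(sim$counts)
  cl <- cluster_samples(norm$log2, k = "auto")
  expect_equal(cl$k, 4)
  expect_equal(ari(cl$labels, sim$truth$cluster_labels), 1.0)
  expect_true(all(abs(cl$distance - t(cl$distance)) < 1e-12))
  expect_true(all(diag(cl$distance) == 0))
  expect_true(all(cl$distance >= 0 & cl$distance <= 2))
})

test_that("classical MDS embeds symmetric geometries faithfully", {
  # three equidistant points
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  xy <- mds_coordinates(d3)
  emb <- as.matrix(dist(xy))
  expect_equal(emb[upper.tri(emb)], rep(emb[1, 2], 3), tolerance = 1e-9)

  # collinear points embed on a line (second coordinate ~ 0)
  dl <- as.matrix(dist(c(0, 2, 5)))
  dimnames(dl) <- list(letters[1:3], letters[1:3])
  xyl <- mds_coordinates(dl)
  expect_equal(unname(xyl[, "y"]), rep(0, 3), tolerance = 1e-6)
  expect_equal(unname(sort(as.matrix(dist(xyl[, "x"]))[1, ])),
               unname(sort(dl[1, ])), tolerance = 1e-6)

  # duplicated samples get identical coordinates
  d4 <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3)
  dimnames(d4) <- list(letters[1:3], letters[1:3])
  xyd <- mds_coordinates(d4)
  expect_equal(xyd["a", ], xyd["b", ], ignore_attr = TRUE)

  ns <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(mds_coordinates(ns), "symmetric")
})

test_that("DE screen recovers planted markers with controlled false positives", {
  sim <- simulate_expression(1000, c(8, 21), 50, lfc = 3, seed = 11)
  norm <- median_ratio_normalize(sim$counts)
  hits <- de_screen(norm, sim$truth$cluster_labels, 1)
  markers <- sim$truth$de_genes$cluster1
  expect_gte(mean(markers %in% hits$gene), 0.9)
  fp <- setdiff(hits$gene, markers)
  expect_lte(length(fp) / (1000 - 50), 0.05)
  # q-values are monotone in p and never smaller than p
  all_tbl <- attr(hits, "all")
  o <- order(all_tbl$p)
  expect_true(all(diff(all_tbl$q[o]) >= -1e-12))
  expect_true(all(all_tbl$q >= all_tbl$p - 1e-12))
  expect_equal(all_tbl$q, bh_brute(all_tbl$p), tolerance = 1e-12)
})

test_that("permuted labels yield no DE calls in most seeds", {
  sim <- simulate_expression(500, c(8, 21), 50, lfc = 3, seed = 3)
  norm <- median_ratio_normalize(sim$counts)
  n_hit <- vapply(1:10, function(s) {
    set.seed(s)
    perm <- setNames(sample(sim$truth$cluster_labels),
                     names(sim$truth$cluster_labels))
    nrow(de_screen(norm, perm, 1))
  }, numeric(1))
  expect_gte(sum(n_hit == 0), 9)
})

test_that("a gene identical across samples is never a DE hit", {
  sim <- simulate_expression(100, c(4, 4), 10, lfc = 2, seed = 2)
  counts <- sim$counts
  counts["G0001", ] <- 50L
  norm <- median_ratio_normalize(counts)
  hits <- de_screen(norm, sim$truth$cluster_labels, 1)
  expect_false("G0001" %in% hits$gene)
  expect_error(de_screen(norm, sim$truth$cluster_labels, 99), "not in labels")
})

test_that("marker comparison flags direction, significance and missing genes", {
  set.seed(8)
  counts <- matrix(rnbinom(300, mu = 100, size = 5) + 1L, 30, 10,
                   dimnames = list(sprintf("g%d", 1:30), sprintf("s%d", 1:10)))
  counts["g1", 1:5] <- counts["g1", 6:10] * 10L
  norm <- median_ratio_normalize(counts)
  res <- compare_marker_genes(norm, c("g1", "g2", "nope"),
                              sprintf("s%d", 1:5), sprintf("s%d", 6:10))
  expect_equal(res$status, c("ok", "ok", "missing"))
  expect_equal(res$higher_in[1], "A")
  expect_lt(res$p[1], 0.05)
  # rank-sum oracle for the first gene
  w <- wilcox.test(norm$normalized["g1", 1:5], norm$normalized["g1", 6:10],
                   exact = FALSE)
  expect_equal(res$p[1], w$p.value)
  expect_equal(nrow(compare_marker_genes(norm, character(0),
                                         sprintf("s%d", 1:5),
                                         sprintf("s%d", 6:10))), 0)
  expect_error(compare_marker_genes(norm, "g1", "s1", c("s1", "s2")),
               "disjoint")
})
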