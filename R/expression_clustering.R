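## Expression normalization, variable-gene filtering, Spearman/Ward.D2
## clustering with elbow selection of k, classical MDS, and rank-based
## differential expression / marker screens.

#' Median-of-ratios normalization of a counts matrix
#'
#' Size factors follow the median-of-ratios scheme: for each sample, the
#' median over genes (restricted to genes with nonzero counts in every
#' sample, so the geometric mean reference is finite) of the ratio of the
#' sample's count to the gene's geometric mean across samples. A sample
#' identical to the pseudo-reference gets size factor 1. The log2 slab is
#' `log2(normalized + 1)`.
#'
#' @param counts Integer matrix (genes x samples), >= 2 samples, with at
#'   least one gene expressed (> 0) in every sample.
#' @return An object of class `sts_norm`: list with `size_factors`,
#'   `normalized` (counts / size factor) and `log2`.
#' @export
#' @examples
#' m <- cbind(s1 = c(10, 20, 40), s2 = c(20, 40, 80))
#' rownames(m) <- c("a", "b", "c")
#' median_ratio_normalize(m)$size_factors
median_ratio_normalize <- function(counts) {
  if (ncol(counts) < 2) stop("need at least 2 samples")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop("no gene with nonzero counts in all samples; cannot form reference")
  }
  sub <- counts[all_pos, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))                # per-gene geometric mean
  sf <- apply(sub, 2, function(col) median(col / ref))
  normalized <- sweep(counts, 2, sf, "/")
  structure(list(size_factors = sf,
                 normalized = normalized,
                 log2 = log2(normalized + 1)),
            class = "sts_norm")
}

#' @export
print.sts_norm <- function(x, ...) {
  cat("Median-of-ratios normalized matrix:", nrow(x$normalized), "genes x",
      ncol(x$normalized), "samples\n")
  cat("  size factors:", paste(sprintf("%.3f", x$size_factors), collapse = " "),
      "\n")
  invisible(x)
}

#' Filter genes by mean and variance of log2 expression
#'
#' Retains genes whose per-gene mean of `log2(normalized + 1)` exceeds
#' `mean_min` and whose sample variance (n-1 denominator) of the same
#' values exceeds `var_min`. Both thresholds are on the log2 scale.
#'
#' @param norm An `sts_norm` object (or a log2 matrix).
#' @param mean_min Minimum mean log2 expression (default 2).
#' @param var_min Minimum log2-scale variance (default 5).
#' @return Character vector of retained gene IDs.
#' @export
filter_variable_genes <- function(norm, mean_min = 2, var_min = 5) {
  l2 <- if (inherits(norm, "sts_norm")) norm$log2 else norm
  mu <- rowMeans(l2)
  v <- apply(l2, 1, var)
  rownames(l2)[mu > mean_min & v > var_min]
}

# within-cluster dispersion of a distance matrix cut at k clusters:
# sum over clusters of mean pairwise squared distance (Ward-consistent)
wss_at_k <- function(d, labels) {
  total <- 0
  for (k in unique(labels)) {
    idx <- which(labels == k)
    if (length(idx) < 2) next
    sub <- d[idx, idx]
    total <- total + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  total
}

#' Hierarchically cluster samples on Spearman correlation distance
#'
#' Pairwise distance is `1 - Spearman rho` between sample expression
#' profiles (average ranks on ties); agglomeration uses Ward's minimum
#' variance criterion (`ward.D2`). With `k = "auto"` the cluster number is
#' chosen by the elbow method: the within-cluster dispersion curve
#' `WSS(k)` is computed from cutting the dendrogram at `k = 1..k_max` and
#' the selected k maximizes the second difference
#' `WSS(k-1) - 2 WSS(k) + WSS(k+1)`.
#'
#' @param log2matrix Genes x samples matrix of log2 expression (typically
#'   the `log2` slab of [median_ratio_normalize()] restricted to
#'   [filter_variable_genes()]), or an `sts_norm` object.
#' @param k Number of clusters, or `"auto"` for elbow selection.
#' @param k_max Largest k scanned when `k = "auto"` (default 10).
#' @return An object of class `sts_clust`: list with `k`, `labels` (named
#'   integer vector), `merge_heights`, `wss_curve`, `distance` (sample x
#'   sample matrix in `[0, 2]`) and the `hclust` tree.
#' @export
cluster_samples <- function(log2matrix, k = "auto", k_max = 10) {
  m <- if (inherits(log2matrix, "sts_norm")) log2matrix$log2 else log2matrix
  if (nrow(m) < 2) stop("need at least 2 genes to cluster on")
  if (ncol(m) < 3) stop("need at least 3 samples to cluster")
  const <- apply(m, 2, function(x) var(x) == 0)
  if (any(const)) {
    stop("constant expression profile (Spearman rho undefined) for: ",
         paste(colnames(m)[const], collapse = ", "))
  }
  rho <- cor(m, method = "spearman")
  d <- 1 - rho
  # numerical guard: symmetrize and zero the diagonal
  d <- (d + t(d)) / 2
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "ward.D2")
  k_max <- min(k_max, ncol(m) - 1)
  wss <- vapply(seq_len(k_max + 1), function(kk) {
    wss_at_k(d, cutree(hc, k = min(kk, ncol(m))))
  }, numeric(1))
  names(wss) <- seq_along(wss)
  if (identical(k, "auto")) {
    ks <- 2:k_max
    second_diff <- wss[ks - 1] - 2 * wss[ks] + wss[ks + 1]
    k <- ks[which.max(second_diff)]
  } else {
    k <- as.integer(k)
    if (k < 2 || k > ncol(m)) stop("k out of range")
  }
  labels <- cutree(hc, k = k)
  structure(list(k = k, labels = labels, merge_heights = hc$height,
                 wss_curve = wss, distance = d, hclust = hc),
            class = "sts_clust")
}

#' @export
print.sts_clust <- function(x, ...) {
  cat("Sample clustering (Spearman distance, Ward.D2)\n")
  cat("  samples:", length(x$labels), " k:", x$k, "\n")
  cat("  cluster sizes:", paste(table(x$labels), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.sts_clust <- function(x, ...) {
  plot(x$hclust, main = "Spearman / Ward.D2 clustering", xlab = "",
       sub = "", ...)
  invisible(x)
}

#' Classical (Torgerson) MDS coordinates of a distance matrix
#'
#' @param distance Symmetric sample x sample distance matrix.
#' @return A samples x 2 matrix of centered coordinates.
#' @export
mds_coordinates <- function(distance) {
  if (!isSymmetric(unname(as.matrix(distance)), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  xy <- cmdscale(as.dist(distance), k = 2)
  if (ncol(xy) < 2) xy <- cbind(xy, 0)  # degenerate (collinear) geometry
  colnames(xy) <- c("x", "y")
  xy
}

#' One-vs-rest differential expression screen
#'
#' For each gene, the log2 fold change is the difference in mean log2
#' normalized expression between the target cluster and all remaining
#' samples, and the p-value comes from a two-sided Wilcoxon rank-sum test
#' on the log2 values; q-values are Benjamini-Hochberg across all genes.
#' Returned rows are the up-regulated screen hits
#' (`log2FC > lfc_min & q < q_max`); the full table is attached as
#' attribute `"all"`.
#'
#' @param norm An `sts_norm` object.
#' @param labels Named cluster labels covering the samples.
#' @param target The cluster compared against the rest.
#' @param lfc_min Minimum log2 fold change (default 2).
#' @param q_max BH q-value cutoff (default 0.05).
#' @return `data.frame` with `gene`, `log2FC`, `p`, `q`, `direction`.
#' @export
de_screen <- function(norm, labels, target, lfc_min = 2, q_max = 0.05) {
  l2 <- norm$log2
  labels <- labels[colnames(l2)]
  if (!target %in% labels) stop("target cluster '", target, "' not in labels")
  in_t <- labels == target
  if (sum(in_t) < 2 || sum(!in_t) < 2) stop("both groups need >= 2 samples")
  lfc <- rowMeans(l2[, in_t, drop = FALSE]) - rowMeans(l2[, !in_t, drop = FALSE])
  p <- apply(l2, 1, function(x) {
    if (var(x) == 0) return(1)
    suppressWarnings(wilcox.test(x[in_t], x[!in_t], exact = FALSE)$p.value)
  })
  q <- p.adjust(p, method = "BH")
  all <- data.frame(gene = rownames(l2), log2FC = lfc, p = p, q = q,
                    direction = ifelse(lfc >= 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  hits <- all[all$log2FC > lfc_min & all$q < q_max, , drop = FALSE]
  hits <- hits[order(hits$q, -hits$log2FC), ]
  rownames(hits) <- NULL
  attr(hits, "all") <- all
  hits
}

#' Compare candidate marker genes between two sample groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test on normalized counts between
#' two disjoint groups, BH-adjusted across the tested genes. Genes absent
#' from the matrix are listed with status `"missing"`, never dropped
#' silently.
#'
#' @param norm An `sts_norm` object.
#' @param genes Candidate marker gene IDs.
#' @param groupA,groupB Disjoint sample ID sets, each of size >= 2.
#' @return `data.frame` with `gene`, `meanA`, `meanB`, `p`, `q`,
#'   `higher_in`, `status`.
#' @export
compare_marker_genes <- function(norm, genes, groupA, groupB) {
  if (length(intersect(groupA, groupB)) > 0) stop("groups must be disjoint")
  if (length(groupA) < 2 || length(groupB) < 2) {
    stop("each group needs >= 2 samples")
  }
  nm <- norm$normalized
  if (length(genes) == 0) {
    return(data.frame(gene = character(0), meanA = numeric(0),
                      meanB = numeric(0), p = numeric(0), q = numeric(0),
                      higher_in = character(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(gene = as.character(genes), meanA = NA_real_,
                    meanB = NA_real_, p = NA_real_, q = NA_real_,
                    higher_in = NA_character_, status = "ok",
                    stringsAsFactors = FALSE)
  present <- out$gene %in% rownames(nm)
  out$status[!present] <- "missing"
  for (i in which(present)) {
    a <- nm[out$gene[i], groupA]
    b <- nm[out$gene[i], groupB]
    out$meanA[i] <- mean(a)
    out$meanB[i] <- mean(b)
    out$p[i] <- if (var(c(a, b)) == 0) 1 else
      suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    out$higher_in[i] <- if (out$meanA[i] >= out$meanB[i]) "A" else "B"
  }
  out$q[present] <- p.adjust(out$p[present], method = "BH")
  out
}
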