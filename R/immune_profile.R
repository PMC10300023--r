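## MPAS scoring, immunogenomic correlation matrix, CD3 cluster tests and
## the CD3-correlated gene screen.

#' The default MPAS gene panel
#'
#' Ten transcriptional targets downstream of MAPK signaling whose combined
#' z-scored expression quantifies pathway activity.
#'
#' @return Character vector of 10 gene symbols.
#' @export
mpas_panel <- function() {
  c("CCND1", "DUSP4", "DUSP6", "EPHA2", "EPHA4", "ETV4", "ETV5",
    "PHLDA1", "SPRY2", "SPRY4")
}

#' MAPK Pathway Activity Score (MPAS)
#'
#' Per sample, the sum of the panel genes' z-scored expression divided by
#' the square root of the panel size:
#' `MPAS = sum(z[panel, sample]) / sqrt(length(panel))`.
#'
#' @param z Genes x samples Z matrix from [zscore_expression()].
#' @param panel Gene panel (default [mpas_panel()]).
#' @return Named numeric vector, sample -> score.
#' @export
#' @examples
#' z <- matrix(1, 10, 3, dimnames = list(mpas_panel(), c("a", "b", "c")))
#' mpas_score(z) # 10 / sqrt(10) = sqrt(10) per sample
mpas_score <- function(z, panel = mpas_panel()) {
  missing <- setdiff(panel, rownames(z))
  if (length(missing) > 0) {
    stop("panel gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  colSums(z[panel, , drop = FALSE]) / sqrt(length(panel))
}

#' Pairwise correlation matrix over immune and genomic variables
#'
#' Pearson correlations (binary 0/1 flags enter as point-biserial) over
#' every pair of numeric variables in an immune profile table, with
#' two-sided p-values and Benjamini-Hochberg q-values computed across the
#' upper triangle. Pairs involving a constant variable are untested and
#' recorded as such.
#'
#' @param profiles Immune profile `data.frame` (see
#'   [read_immune_profiles()]); all numeric columns except `sample_id` are
#'   used.
#' @param q_max Significance cutoff on q (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `sts_corrmat`: list with `variables`, `r`,
#'   `p`, `q`, `significant` matrices and `untested` pair list.
#' @export
immune_correlation_matrix <- function(profiles, q_max = 0.05,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  num <- vapply(profiles, is.numeric, logical(1))
  num["sample_id"] <- FALSE
  vars <- names(profiles)[num]
  X <- as.matrix(profiles[, vars, drop = FALSE])
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples")
  k <- length(vars)
  r <- p <- q <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  untested <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (sd(X[, i]) == 0 || sd(X[, j]) == 0) {
        untested[[length(untested) + 1L]] <- c(vars[i], vars[j])
        next
      }
      ct <- suppressWarnings(cor.test(X[, i], X[, j], method = method,
                                      exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  up <- upper.tri(p)
  q[up] <- p.adjust(p[up], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  sig <- !is.na(q) & q < q_max
  structure(list(variables = vars, r = r, p = p, q = q, significant = sig,
                 q_max = q_max, method = method, untested = untested),
            class = "sts_corrmat")
}

#' @export
print.sts_corrmat <- function(x, ...) {
  cat("Immunogenomic correlation matrix (", x$method, ")\n", sep = "")
  cat("  variables:", length(x$variables), "\n")
  cat("  significant pairs at q <", x$q_max, ":",
      sum(x$significant[upper.tri(x$significant)]), "\n")
  if (length(x$untested) > 0) {
    cat("  untested (constant) pairs:", length(x$untested), "\n")
  }
  invisible(x)
}

#' Kruskal-Wallis test of CD3 density across clusters
#'
#' Rank-based (tie-corrected) Kruskal-Wallis H across clusters, followed by
#' pairwise two-sided Wilcoxon rank-sum tests BH-adjusted across all
#' cluster pairs. Singleton clusters stay in the global test but are
#' excluded from the pairwise comparisons with a warning.
#'
#' @param cd3 Named numeric vector of per-sample CD3 densities.
#' @param clusters Named cluster labels over the same samples.
#' @return List with `statistic`, `p`, and `pairwise` (`data.frame`
#'   groupA/groupB/p/q).
#' @export
cd3_cluster_test <- function(cd3, clusters) {
  shared <- intersect(names(cd3), names(clusters))
  if (length(shared) > 0) {
    cd3 <- cd3[shared]; clusters <- clusters[shared]
  }
  g <- factor(clusters)
  if (nlevels(g) < 2) stop("need >= 2 clusters")
  if (length(cd3) != length(g)) stop("cd3 and clusters must align")
  kw <- if (length(unique(cd3)) == 1) {
    # all observations tied: no evidence of difference by convention
    list(statistic = c(H = 0), p.value = 1)
  } else {
    kruskal.test(cd3, g)
  }
  sizes <- table(g)
  usable <- names(sizes)[sizes >= 2]
  if (length(usable) < nlevels(g)) {
    warning("singleton cluster(s) excluded from pairwise tests: ",
            paste(setdiff(names(sizes), usable), collapse = ", "))
  }
  pairs <- if (length(usable) >= 2) t(combn(usable, 2)) else
    matrix(character(0), 0, 2)
  pw <- data.frame(groupA = pairs[, 1], groupB = pairs[, 2],
                   p = rep(NA_real_, nrow(pairs)),
                   q = rep(NA_real_, nrow(pairs)), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pw))) {
    a <- cd3[g == pw$groupA[i]]
    b <- cd3[g == pw$groupB[i]]
    pw$p[i] <- if (var(c(a, b)) == 0) 1 else
      suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }
  pw$q <- p.adjust(pw$p, method = "BH")
  list(statistic = unname(kw$statistic), p = kw$p.value, pairwise = pw)
}

# vectorized per-row Pearson correlation against one vector, with the
# t-distribution two-sided p-value
row_cor_test <- function(m, y) {
  n <- length(y)
  ys <- (y - mean(y)) / sd(y)
  mc <- m - rowMeans(m)
  msd <- sqrt(rowSums(mc^2) / (n - 1))
  r <- as.vector(mc %*% ys) / ((n - 1) * msd)
  r[msd == 0] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  # |r| = 1 exactly: p underflows to 0, which is the correct limit
  p[!is.na(r) & abs(r) >= 1] <- 0
  data.frame(r = r, p = p)
}

#' Screen genes for correlation with CD3 density
#'
#' Per-gene Pearson correlation between z-scored expression and the IHC CD3
#' density, BH-adjusted over all tested genes, split into positively and
#' negatively correlated lists at `q < q_max`.
#'
#' @param z Genes x samples Z matrix.
#' @param cd3 Named CD3 density vector covering the samples.
#' @param q_max BH q cutoff (default 0.05).
#' @return List with `positive`, `negative` (gene ID vectors) and `table`
#'   (per-gene `r`, `p`, `q`).
#' @export
cd3_gene_screen <- function(z, cd3, q_max = 0.05) {
  shared <- intersect(colnames(z), names(cd3))
  if (length(shared) < 4) stop("need >= 4 shared samples")
  m <- z[, shared, drop = FALSE]
  y <- cd3[shared]
  res <- row_cor_test(m, y)
  res$gene <- rownames(m)
  res$q <- NA_real_
  tested <- !is.na(res$r)
  res$q[tested] <- p.adjust(res$p[tested], method = "BH")
  sig <- tested & res$q < q_max
  list(positive = res$gene[sig & res$r > 0],
       negative = res$gene[sig & res$r < 0],
       table = res[, c("gene", "r", "p", "q")])
}
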