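## Copy-number dosage analysis: z-scored expression, amplitude-expression
## correlation screening, and amplified/deleted gene imbalance testing.

#' Z-score expression per gene across samples
#'
#' Per-gene standardization of the log2 normalized expression:
#' `(x - mean) / sd`, with the n-1 sample standard deviation. Constant
#' genes are set to all-zero rows and flagged.
#'
#' @param norm An `sts_norm` object or a genes x samples matrix of log2
#'   expression.
#' @return Genes x samples Z matrix with attribute `"constant_genes"`.
#' @export
zscore_expression <- function(norm) {
  m <- if (inherits(norm, "sts_norm")) norm$log2 else norm
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd)
  const <- sdv == 0
  sdv[const] <- 1
  z <- (m - mu) / sdv
  z[const, ] <- 0
  attr(z, "constant_genes") <- rownames(m)[const]
  z
}

#' Correlate CNV amplitudes with z-scored expression
#'
#' For each gene in the CNV table that is present in the expression matrix,
#' the Pearson correlation between its per-sample amplitude vector and its
#' z-scored expression over the shared samples, with a two-sided p-value
#' and Benjamini-Hochberg q across all tested genes. A gene passes the
#' dosage screen when its correlation is positive and `q < q_max`. Genes
#' absent from the expression matrix (or with fewer than 3 shared samples,
#' or a constant vector) are recorded as untested, never dropped.
#'
#' @param cnv An `sts_cnv` object (see [read_cnv_table()]).
#' @param z Z matrix from [zscore_expression()].
#' @param q_max BH q cutoff for `passes` (default 0.05).
#' @return `data.frame` with `gene`, `direction`, `n`, `r`, `p`, `q`,
#'   `passes`, `status`.
#' @export
correlate_cnv_expression <- function(cnv, z, q_max = 0.05) {
  genes <- cnv$info$gene
  out <- data.frame(gene = genes, direction = cnv$info$direction,
                    n = NA_integer_, r = NA_real_, p = NA_real_,
                    q = NA_real_, passes = FALSE, status = "untested",
                    stringsAsFactors = FALSE)
  shared <- intersect(colnames(cnv$amplitudes), colnames(z))
  for (i in seq_along(genes)) {
    g <- genes[i]
    if (!g %in% rownames(z)) next
    a <- cnv$amplitudes[g, shared]
    e <- z[g, shared]
    out$n[i] <- length(shared)
    if (length(shared) < 3 || sd(a) == 0 || sd(e) == 0) next
    ct <- cor.test(a, e, method = "pearson")
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
    out$status[i] <- "tested"
  }
  tested <- out$status == "tested"
  out$q[tested] <- p.adjust(out$p[tested], method = "BH")
  out$passes <- tested & !is.na(out$q) & out$r > 0 & out$q < q_max
  out
}

#' Test amplified/deleted gene-count imbalance
#'
#' Counts amplified (amplitude > 0) and deleted (amplitude < 0) genes per
#' sample, and tests whether amplifications dominate. The default
#' reconstruction is a paired two-sided t-test on the per-sample
#' differences (amp count - del count); a one-sample two-sided binomial
#' test on cohort-wide gene counts is available with
#' `per_sample = FALSE`.
#'
#' @param cnv An `sts_cnv` object.
#' @param per_sample Use the paired per-sample t-test (default `TRUE`).
#' @return List with `prop_amplified` (cohort proportion of amplified
#'   gene-sample events), `statistic`, `p`, `method`, and the per-sample
#'   count table when applicable.
#' @export
amp_del_imbalance <- function(cnv, per_sample = TRUE) {
  amp_mat <- cnv$amplitudes
  if (per_sample) {
    if (ncol(amp_mat) < 2) stop("per-sample test needs >= 2 samples")
    amp_n <- colSums(amp_mat > 0)
    del_n <- colSums(amp_mat < 0)
    diffs <- amp_n - del_n
    prop <- sum(amp_n) / (sum(amp_n) + sum(del_n))
    if (all(diffs == diffs[1]) && sd(diffs) == 0) {
      # zero-variance differences: no evidence either way by convention
      p <- if (diffs[1] == 0) 1 else 0
      stat <- NA_real_
    } else {
      tt <- t.test(diffs, mu = 0, alternative = "two.sided")
      p <- tt$p.value
      stat <- unname(tt$statistic)
    }
    list(prop_amplified = prop, statistic = stat, p = p,
         method = "paired t-test on per-sample amp-del counts",
         per_sample_counts = data.frame(sample_id = colnames(amp_mat),
                                        amplified = amp_n, deleted = del_n,
                                        row.names = NULL))
  } else {
    amp_total <- sum(amp_mat > 0)
    del_total <- sum(amp_mat < 0)
    bt <- binom.test(amp_total, amp_total + del_total, p = 0.5)
    list(prop_amplified = amp_total / (amp_total + del_total),
         statistic = amp_total, p = bt$p.value,
         method = "binomial test on pooled gene counts")
  }
}
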