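# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# adjusted Rand index from the contingency-table formula
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

# brute-force Kruskal-Wallis H with tie correction, straight from the rank
# formula
kw_brute <- function(x, g) {
  g <- factor(g)
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / corr
}

# hand Benjamini-Hochberg: q_i = min over j >= i of p_(j) * m / j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# hand median-of-ratios size factors
size_factors_brute <- function(counts) {
  keep <- apply(counts, 1, function(x) all(x > 0))
  ref <- exp(rowMeans(log(counts[keep, , drop = FALSE])))
  apply(counts[keep, , drop = FALSE], 2, function(col) median(col / ref))
}

# column-by-column cosine table computed longhand
cosine_matrix_oracle <- function(A, B) {
  out <- matrix(NA_real_, ncol(A), ncol(B))
  for (i in seq_len(ncol(A))) {
    for (j in seq_len(ncol(B))) {
      out[i, j] <- sum(A[, i] * B[, j]) /
        (sqrt(sum(A[, i]^2)) * sqrt(sum(B[, j]^2)))
    }
  }
  out
}

# a tiny hand-built genome whose sequence is chosen per test
tiny_genome <- function(seqs) {
  structure(list(contigs = seqs,
                 genes = data.frame(gene_id = character(0),
                                    contig = character(0), start = integer(0),
                                    end = integer(0), strand = character(0),
                                    stringsAsFactors = FALSE)),
            class = "sts_genome")
}

# simulate a 96 x n catalog by pure multinomial draws from given profiles;
# independent of simulate_mutations
catalog_from_profiles <- function(profiles, assigned, n_mut, seed) {
  set.seed(seed)
  counts <- vapply(seq_along(assigned), function(j) {
    rmultinom(1, n_mut[j], profiles[, assigned[j]])[, 1]
  }, numeric(96))
  rownames(counts) <- rownames(profiles)
  colnames(counts) <- sprintf("S%02d", seq_along(assigned))
  counts
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
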