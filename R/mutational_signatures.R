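## 96-context mutation catalogs, de novo signature extraction by
## Kullback-Leibler NMF, and cosine-similarity naming/assignment against a
## reference signature set.

#' Build a 96-trinucleotide-context catalog from SNV calls
#'
#' Each single-base substitution is assigned to one of the 96 canonical
#' pyrimidine-strand contexts using the flanking bases from the reference
#' genome; substitutions reported with a purine reference allele are
#' reverse-complemented first. Records whose REF or ALT allele is longer
#' than one base (indels) are skipped with a logged count. The reference
#' base at each position must match the genome.
#'
#' @param variants `data.frame` with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `sample_id` (from [read_vcf()] or [simulate_mutations()]).
#' @param genome An `sts_genome` object or the path to a FASTA file.
#' @return Integer 96 x samples matrix with context row names in canonical
#'   order; each column sums to the sample's SNV count. The number of
#'   ignored indels is attached as attribute `"n_indels_ignored"`.
#' @export
build_catalog <- function(variants, genome) {
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  contexts <- trinucleotide_contexts()
  samples <- sort(unique(variants$sample_id))
  catalog <- matrix(0L, 96, length(samples),
                    dimnames = list(contexts, samples))
  if (nrow(variants) == 0) return(catalog)
  is_snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref %in% c("A", "C", "G", "T") &
    variants$alt %in% c("A", "C", "G", "T")
  n_indel <- sum(!is_snv)
  if (n_indel > 0) {
    sts_log(n_indel, " non-SNV record(s) ignored in catalog",
            stage = "catalog")
  }
  v <- variants[is_snv, , drop = FALSE]
  if (nrow(v) == 0) {
    attr(catalog, "n_indels_ignored") <- n_indel
    return(catalog)
  }
  missing_ctg <- setdiff(unique(v$chrom), names(genome$contigs))
  if (length(missing_ctg) > 0) {
    stop("contig(s) absent from genome: ", paste(missing_ctg, collapse = ", "))
  }
  clen <- nchar(genome$contigs)[v$chrom]
  if (any(v$pos < 2 | v$pos > clen - 1)) {
    bad <- which(v$pos < 2 | v$pos > clen - 1)[1]
    stop("variant at contig edge, context unresolvable: ",
         v$chrom[bad], ":", v$pos[bad])
  }
  p5 <- substr(genome$contigs[v$chrom], v$pos - 1, v$pos - 1)
  refg <- substr(genome$contigs[v$chrom], v$pos, v$pos)
  p3 <- substr(genome$contigs[v$chrom], v$pos + 1, v$pos + 1)
  if (any(refg != v$ref)) {
    bad <- which(refg != v$ref)[1]
    stop("REF allele mismatches genome at ", v$chrom[bad], ":", v$pos[bad],
         " (VCF ", v$ref[bad], ", genome ", refg[bad], ")")
  }
  ctx <- snv_context(v$ref, v$alt, p5, p3)
  tab <- table(factor(ctx, levels = contexts),
               factor(v$sample_id, levels = samples))
  catalog[] <- as.integer(tab)
  attr(catalog, "n_indels_ignored") <- n_indel
  catalog
}

#' Collapse a 96-context catalog to the 6 substitution classes
#'
#' @param catalog 96 x samples matrix from [build_catalog()].
#' @return 6 x samples matrix of substitution-class counts.
#' @export
collapse_classes <- function(catalog) {
  cls <- substr(rownames(catalog), 3, 5)
  out <- rowsum(catalog, group = factor(cls, levels = substitution_classes()))
  out[substitution_classes(), , drop = FALSE]
}

# one KL-NMF run: Brunet multiplicative updates minimizing the generalized
# Kullback-Leibler divergence D(V || WH); the objective is checked every
# iteration and must be non-increasing (up to numerical eps)
nmf_kl_once <- function(V, k, max_iter, tol, eps = 1e-12) {
  n <- nrow(V); m <- ncol(V)
  W <- matrix(runif(n * k, 0.1, 1), n, k)
  H <- matrix(runif(k * m, 0.1, 1), k, m)
  kl_div <- function(WH) {
    sum(ifelse(V > 0, V * log(V / WH), 0) - V + WH)
  }
  WH <- W %*% H + eps
  obj <- kl_div(WH)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # H update
    H <- H * (t(W) %*% (V / WH)) / (colSums(W) + eps)
    WH <- W %*% H + eps
    # W update
    W <- W * ((V / WH) %*% t(H)) / matrix(rowSums(H) + eps, n, k, byrow = TRUE)
    WH <- W %*% H + eps
    new_obj <- kl_div(WH)
    trace <- c(trace, new_obj)
    if (new_obj > obj + 1e-8 * (abs(obj) + 1)) {
      warning("KL objective increased at iteration ", it)
    }
    if (abs(obj - new_obj) < tol * (abs(obj) + 1e-10)) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  list(W = W, H = H, objective = obj, trace = trace)
}

# Frobenius (Lee-Seung) multiplicative updates, available behind a flag
nmf_frobenius_once <- function(V, k, max_iter, tol, eps = 1e-12) {
  n <- nrow(V); m <- ncol(V)
  W <- matrix(runif(n * k, 0.1, 1), n, k)
  H <- matrix(runif(k * m, 0.1, 1), k, m)
  obj <- sum((V - W %*% H)^2)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% H %*% t(H) + eps)
    new_obj <- sum((V - W %*% H)^2)
    trace <- c(trace, new_obj)
    if (abs(obj - new_obj) < tol * (abs(obj) + 1e-10)) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  list(W = W, H = H, objective = obj, trace = trace)
}

# mean per-sample cosine between catalog columns and their reconstruction
reconstruction_cosine <- function(V, W, H) {
  R <- W %*% H
  mean(vapply(seq_len(ncol(V)), function(j) {
    if (sum(V[, j]) == 0) return(1)
    cosine_similarity(V[, j], R[, j])
  }, numeric(1)))
}

#' Extract de novo mutational signatures by NMF
#'
#' Factorizes the catalog `V ~ W H` (signatures x exposures) by
#' multiplicative updates minimizing the generalized Kullback-Leibler
#' divergence, keeping the best of `n_restarts` random restarts by final
#' objective. Signature columns of `W` are normalized to sum 1, with `H`
#' rescaled compensatingly so `W H` is unchanged.
#'
#' When `rank` is a range, each rank is run with the full restart budget
#' and the smallest rank is chosen whose gain in explained cosine
#' reconstruction (1 - mean per-sample reconstruction distance) over the
#' previous rank falls below 0.02.
#'
#' @param catalog 96 x samples count matrix (>= 2 samples with positive
#'   column sums).
#' @param rank Number of signatures, or an integer range (e.g. `2:5`).
#' @param n_restarts Random restarts per rank (default 100).
#' @param max_iter Maximum multiplicative-update iterations (default 2000).
#' @param tol Relative objective-change convergence tolerance.
#' @param seed Integer seed; extraction is deterministic given
#'   `(seed, n_restarts)`.
#' @param method `"kl"` (default) or `"frobenius"`.
#' @return An object of class `sts_signatures`: list with `profiles`
#'   (96 x K, columns sum to 1), `exposures` (K x samples), `names`,
#'   `objective`, `objective_trace` (best run), `rank_metrics` (when a
#'   range was given), and `method`.
#' @export
extract_signatures <- function(catalog, rank, n_restarts = 100,
                               max_iter = 2000, tol = 1e-6, seed = 1,
                               method = c("kl", "frobenius")) {
  method <- match.arg(method)
  V <- as.matrix(catalog)
  storage.mode(V) <- "double"
  if (ncol(V) < 2) stop("need at least 2 samples")
  if (any(colSums(V) == 0)) stop("catalog has empty sample column(s)")
  if (max(rank) >= min(nrow(V), ncol(V))) {
    stop("rank must be below min(contexts, samples)")
  }
  runner <- if (method == "kl") nmf_kl_once else nmf_frobenius_once

  run_rank <- function(k, seed_base) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      set.seed(seed_base + r)
      fit <- runner(V, k, max_iter, tol)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    best
  }

  ranks <- sort(unique(as.integer(rank)))
  rank_metrics <- NULL
  if (length(ranks) > 1) {
    scan <- unique(c(max(min(ranks) - 1L, 1L), ranks))
    fits <- list(); metric <- numeric(0)
    for (k in scan) {
      fits[[as.character(k)]] <- run_rank(k, seed + 10000L * k)
      metric[as.character(k)] <- reconstruction_cosine(
        V, fits[[as.character(k)]]$W, fits[[as.character(k)]]$H)
    }
    gain <- diff(metric)
    chosen <- NULL
    for (i in seq_along(gain)) {
      if (gain[i] < 0.02) { chosen <- scan[i + 1] - 1L; break }
    }
    if (is.null(chosen) || chosen < min(ranks)) {
      chosen <- if (is.null(chosen)) max(ranks) else min(ranks)
    }
    rank_metrics <- data.frame(rank = scan, explained_cosine = unname(metric))
    k <- chosen
    best <- fits[[as.character(k)]]
  } else {
    k <- ranks
    best <- run_rank(k, seed)
  }

  scale <- colSums(best$W)
  W <- sweep(best$W, 2, scale, "/")
  H <- sweep(best$H, 1, scale, "*")
  sig_names <- paste0("Signature", LETTERS[seq_len(k)])
  colnames(W) <- sig_names; rownames(W) <- rownames(catalog)
  rownames(H) <- sig_names; colnames(H) <- colnames(catalog)
  ord <- order(-rowSums(H))
  W <- W[, ord, drop = FALSE]; H <- H[ord, , drop = FALSE]
  colnames(W) <- rownames(H) <- paste0("Signature", LETTERS[seq_len(k)])
  structure(list(profiles = W, exposures = H, names = colnames(W),
                 objective = best$objective, objective_trace = best$trace,
                 rank_metrics = rank_metrics, method = method),
            class = "sts_signatures")
}

#' @export
print.sts_signatures <- function(x, ...) {
  cat("Mutational signature set:", ncol(x$profiles), "signature(s) x",
      nrow(x$profiles), "contexts\n")
  if (!is.null(x$exposures)) {
    cat("  exposures over", ncol(x$exposures), "samples\n")
  }
  cat("  names:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Load a reference signature set from a COSMIC-layout file
#'
#' Tab-delimited, first column the 96 context labels (`"A[C>A]A"` form, any
#' order), remaining columns one reference signature each. Columns are
#' re-ordered to canonical context order and renormalized to sum 1.
#'
#' The package ships a small synthetic reference set
#' (`sts_extdata("synthetic_reference_signatures.tsv")`) whose profiles are
#' synthetic stand-ins shaped like familiar SBS processes; a genuine COSMIC
#' file in the same layout loads identically.
#'
#' @param path Path to the signature TSV.
#' @return An `sts_signatures` object (profiles only).
#' @export
read_signature_reference <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  contexts <- trinucleotide_contexts()
  ctx_col <- names(x)[1]
  if (!setequal(x[[ctx_col]], contexts)) {
    stop("first column must contain the 96 canonical context labels")
  }
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[ctx_col]]
  m <- m[contexts, , drop = FALSE]
  if (any(m < 0)) stop("negative signature entries")
  m <- sweep(m, 2, colSums(m), "/")
  structure(list(profiles = m, exposures = NULL, names = colnames(m)),
            class = "sts_signatures")
}

#' @rdname read_signature_reference
#' @param signatures An `sts_signatures` object.
#' @export
write_signature_reference <- function(signatures, path) {
  df <- data.frame(context = rownames(signatures$profiles),
                   signatures$profiles, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Name de novo signatures and assign samples by cosine similarity
#'
#' Each de novo signature is labeled `"<ref>-like"` after the reference
#' signature with the highest cosine similarity to its profile. Each
#' sample's frequency-normalized 96-context profile (raw catalog counts,
#' not NMF exposures) is assigned the reference signature with the highest
#' cosine similarity. Both full cosine tables are returned.
#'
#' @param denovo `sts_signatures` from [extract_signatures()].
#' @param reference `sts_signatures` reference set.
#' @param catalog 96 x samples catalog used for per-sample assignment.
#' @return List with `naming` (`data.frame` denovo/reference/name/cosine),
#'   `assignment` (`data.frame` sample/signature/cosine),
#'   `denovo_cosine` and `sample_cosine` matrices.
#' @export
name_and_assign <- function(denovo, reference, catalog) {
  R <- reference$profiles
  if (is.null(R) || ncol(R) == 0) stop("empty reference signature set")
  D <- denovo$profiles
  dc <- cosine_matrix(D, R)
  naming <- data.frame(
    denovo = colnames(D),
    reference = colnames(R)[apply(dc, 1, which.max)],
    cosine = apply(dc, 1, max),
    stringsAsFactors = FALSE)
  naming$name <- paste0(naming$reference, "-like")

  V <- as.matrix(catalog)
  storage.mode(V) <- "double"
  nonzero <- colSums(V) > 0
  F <- sweep(V[, nonzero, drop = FALSE], 2, colSums(V[, nonzero, drop = FALSE]), "/")
  sc <- cosine_matrix(F, R)
  assignment <- data.frame(
    sample = colnames(F),
    signature = colnames(R)[apply(sc, 1, which.max)],
    cosine = apply(sc, 1, max),
    stringsAsFactors = FALSE)
  list(naming = naming, assignment = assignment,
       denovo_cosine = dc, sample_cosine = sc)
}
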