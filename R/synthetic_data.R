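## Synthetic-data generators. Every input the pipeline consumes can be
## produced here with known ground truth (cluster labels, signature
## exposures, dosage genes, coupled immune fractions), so each analysis
## stage is testable without external downloads. All generators are pure
## functions of (parameters, seed).

#' Generate a miniature reference genome
#'
#' Random-base contigs with non-overlapping gene intervals, used to place
#' simulated somatic mutations and resolve their trinucleotide contexts.
#' With the default 100 kb of sequence all 96 contexts are present with very
#' high probability.
#'
#' @param n_contigs Number of contigs.
#' @param length Total genome length in bases (>= 1000), split evenly.
#' @param n_genes Number of non-overlapping genes to place.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param gc GC fraction of the base composition (default 0.5, uniform).
#' @return An object of class `sts_genome`: list with `contigs` (named
#'   character vector of A/C/G/T strings) and `genes` (`data.frame` with
#'   `gene_id`, `contig`, `start`, `end`, `strand`; 1-based inclusive).
#' @export
#' @examples
#' g <- generate_genome(1, 10000, 5, seed = 1)
#' nchar(g$contigs)
generate_genome <- function(n_contigs, length, n_genes, seed, gc = 0.5) {
  stopifnot(n_contigs >= 1, length >= 1000, n_genes >= 0)
  set.seed(seed)
  contig_len <- rep(length %/% n_contigs, n_contigs)
  contig_len[1] <- contig_len[1] + length %% n_contigs
  names(contig_len) <- sprintf("ctg%d", seq_len(n_contigs))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  contigs <- vapply(contig_len, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))

  # allocate genes round-robin, place each inside an equal-width slot
  min_len <- 100L
  gene_contig <- rep(names(contig_len), length.out = max(n_genes, 0))
  genes <- NULL
  if (n_genes > 0) {
    per <- table(factor(gene_contig, levels = names(contig_len)))
    rows <- list()
    for (ct in names(contig_len)) {
      g <- as.integer(per[[ct]])
      if (g == 0) next
      L <- contig_len[[ct]]
      slot <- L %/% g
      if (slot < min_len + 20L) {
        stop("cannot place ", n_genes, " genes of >= ", min_len,
             " bp on ", length, " bp of sequence")
      }
      for (i in seq_len(g)) {
        lo <- (i - 1L) * slot + 1L
        glen <- sample(seq(min_len, min(slot - 10L, 1500L)), 1)
        start <- lo + sample.int(slot - glen - 5L, 1) - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ct, start = start, end = start + glen - 1L,
          strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      }
    }
    genes <- do.call(rbind, rows)
    genes <- data.frame(gene_id = sprintf("G%04d", seq_len(nrow(genes))),
                        genes, stringsAsFactors = FALSE)
  } else {
    genes <- data.frame(gene_id = character(0), contig = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
  }
  structure(list(contigs = contigs, genes = genes), class = "sts_genome")
}

#' @export
print.sts_genome <- function(x, ...) {
  cat("Synthetic genome:", length(x$contigs), "contig(s),",
      sum(nchar(x$contigs)), "bp,", nrow(x$genes), "genes\n")
  invisible(x)
}

#' Write / read a genome as FASTA
#'
#' @param genome An `sts_genome` object.
#' @param path FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  contigs <- as.character(seqs)
  # keep only the first whitespace-delimited token of each FASTA header
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  structure(list(contigs = contigs,
                 genes = data.frame(gene_id = character(0),
                                    contig = character(0), start = integer(0),
                                    end = integer(0), strand = character(0),
                                    stringsAsFactors = FALSE)),
            class = "sts_genome")
}

#' Simulate a counts matrix with planted cluster structure
#'
#' Counts are negative binomial with variance `mu + mu^2 * dispersion`;
#' gene baseline means are log-normal (meanlog 4, sdlog 1.5) to mimic the
#' dynamic range of bulk RNAseq. Each cluster gets `markers_per_cluster`
#' marker genes whose mean is multiplied by `2^lfc` in that cluster.
#'
#' @param n_genes Number of genes.
#' @param samples_per_cluster Integer vector of cluster sizes (>= 2
#'   clusters); e.g. `c(11, 7, 5, 6)` mimics a 29-tumor cohort.
#' @param markers_per_cluster Marker genes planted per cluster.
#' @param lfc Planted log2 fold change (>= 0; 0 plants no structure).
#' @param dispersion NB dispersion (0 gives Poisson counts).
#' @param seed Integer seed.
#' @return List with `counts` (integer matrix) and `truth` (list with
#'   `cluster_labels`, `de_genes` per cluster, `seed`).
#' @export
#' @examples
#' sim <- simulate_expression(500, c(5, 5, 5), 30, lfc = 3, seed = 1)
#' dim(sim$counts)
simulate_expression <- function(n_genes, samples_per_cluster,
                                markers_per_cluster = 50, lfc = 2,
                                dispersion = 0.15, seed = 1) {
  K <- length(samples_per_cluster)
  if (K < 2) stop("need at least 2 clusters")
  if (lfc < 0) stop("lfc must be >= 0")
  if (markers_per_cluster * K > n_genes) {
    stop("more marker genes than genes")
  }
  set.seed(seed)
  n_samples <- sum(samples_per_cluster)
  labels <- rep(seq_len(K), samples_per_cluster)
  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  names(labels) <- sample_ids
  genes <- sprintf("G%04d", seq_len(n_genes))

  base_mu <- rlnorm(n_genes, meanlog = 4, sdlog = 1.5)
  marker_idx <- matrix(sample.int(n_genes, markers_per_cluster * K),
                       nrow = markers_per_cluster)
  mu <- matrix(base_mu, n_genes, n_samples)
  for (k in seq_len(K)) {
    mu[marker_idx[, k], labels == k] <- mu[marker_idx[, k], labels == k] * 2^lfc
  }
  counts <- if (dispersion > 0) {
    matrix(rnbinom(n_genes * n_samples, mu = mu, size = 1 / dispersion),
           n_genes, n_samples)
  } else {
    matrix(rpois(n_genes * n_samples, lambda = mu), n_genes, n_samples)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(genes, sample_ids)
  de_genes <- lapply(seq_len(K), function(k) genes[marker_idx[, k]])
  names(de_genes) <- paste0("cluster", seq_len(K))
  list(counts = counts,
       truth = list(cluster_labels = labels, de_genes = de_genes, seed = seed))
}

# index of genome positions by pyrimidine-strand trinucleotide; every
# interior position contributes exactly one entry
context_site_index <- function(genome) {
  idx <- list()
  for (ct in names(genome$contigs)) {
    s <- genome$contigs[[ct]]
    n <- nchar(s)
    if (n < 3) next
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    pos <- 2:(n - 1)
    p5 <- ch[pos - 1]; ce <- ch[pos]; p3 <- ch[pos + 1]
    pyr <- ce %in% c("C", "T")
    trip <- ifelse(pyr,
                   paste0(p5, ce, p3),
                   paste0(chartr("ACGT", "TGCA", p3),
                          chartr("ACGT", "TGCA", ce),
                          chartr("ACGT", "TGCA", p5)))
    df <- data.frame(contig = ct, pos = pos, pyr = pyr, trip = trip,
                     stringsAsFactors = FALSE)
    idx[[ct]] <- df
  }
  all <- do.call(rbind, idx)
  split(all[, c("contig", "pos", "pyr")], all$trip)
}

#' Simulate somatic SNVs from mutational signature mixtures
#'
#' For each sample, the number of mutations equals the rounded sum of its
#' signature exposures; each mutation's 96-context is drawn from the
#' sample's exposure-weighted mixture of signature profiles and placed
#' uniformly at a genome position whose flanking bases realize that context
#' (on either strand; purine-reference sites are emitted with the
#' complementary alleles).
#'
#' @param genome An `sts_genome`.
#' @param signatures A 96 x K profile matrix (columns sum to 1) or an
#'   `sts_signatures` object.
#' @param exposures K x S non-negative matrix of per-sample exposures
#'   (column names are sample IDs).
#' @param seed Integer seed.
#' @return List with `variants` (`data.frame` chrom/pos/ref/alt/sample_id)
#'   and `catalog`, the internally sampled 96 x S context-count matrix that
#'   a catalog rebuilt from the emitted variants must reproduce exactly.
#' @export
simulate_mutations <- function(genome, signatures, exposures, seed = 1) {
  W <- if (inherits(signatures, "sts_signatures")) signatures$profiles else signatures
  if (nrow(W) != 96) stop("signature profiles must have 96 rows")
  if (is.null(dim(exposures))) exposures <- matrix(exposures, ncol = 1)
  if (nrow(exposures) != ncol(W)) {
    stop("exposures must have one row per signature")
  }
  samples <- colnames(exposures)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(exposures)))
  contexts <- trinucleotide_contexts()
  set.seed(seed)
  sites <- context_site_index(genome)

  catalog <- matrix(0L, 96, ncol(exposures),
                    dimnames = list(contexts, samples))
  rows <- list()
  for (j in seq_len(ncol(exposures))) {
    n_mut <- round(sum(exposures[, j]))
    if (n_mut == 0) next
    w <- exposures[, j] / sum(exposures[, j])
    p <- as.vector(W %*% w)
    p <- p / sum(p)
    ctx_counts <- rmultinom(1, n_mut, p)[, 1]
    catalog[, j] <- as.integer(ctx_counts)
    for (i in which(ctx_counts > 0)) {
      ctx <- contexts[i]
      p5 <- substr(ctx, 1, 1); ref <- substr(ctx, 3, 3)
      alt <- substr(ctx, 5, 5); p3 <- substr(ctx, 7, 7)
      key <- paste0(p5, ref, p3)
      st <- sites[[key]]
      if (is.null(st) || nrow(st) == 0) {
        stop("context ", ctx, " has no eligible site in the genome")
      }
      pick <- st[sample.int(nrow(st), ctx_counts[i], replace = TRUE), ]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = pick$contig,
        pos = pick$pos,
        ref = ifelse(pick$pyr, ref, chartr("ACGT", "TGCA", ref)),
        alt = ifelse(pick$pyr, alt, chartr("ACGT", "TGCA", alt)),
        sample_id = samples[j],
        stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), sample_id = character(0),
               stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  list(variants = variants, catalog = catalog)
}

# strictly monotone integer counts as a function of a latent score:
# after sorting by the latent order, bump ties so ranks match exactly
monotone_counts <- function(latent, log2_mean, log2_sd) {
  v <- round(2^(log2_mean + log2_sd * latent) - 1)
  v[v < 0] <- 0
  o <- order(latent)
  sv <- v[o]
  for (i in seq_along(sv)[-1]) {
    if (sv[i] <= sv[i - 1]) sv[i] <- sv[i - 1] + 1
  }
  v[o] <- sv
  as.integer(v)
}

#' Simulate gene-level CNV amplitudes with planted dosage coupling
#'
#' A chosen set of dosage genes receives per-sample amplitudes, and their
#' expression counts are rewritten as a strictly monotone function of a
#' latent score correlated with the amplitude at the requested `coupling`,
#' so the downstream amplitude-vs-z-expression Pearson correlation recovers
#' approximately `coupling` (exactly rank-identical at `coupling = 1`).
#' Null genes receive amplitudes independent of expression.
#'
#' @param expr Counts matrix (genes x samples), e.g. from
#'   [simulate_expression()].
#' @param n_dosage_genes Number of genes with planted coupling.
#' @param coupling Target correlation in `(0, 1]`.
#' @param seed Integer seed.
#' @param n_null_genes Number of additional amplitude rows with no coupling
#'   (default `3 * n_dosage_genes`).
#' @return List with `cnv` (an `sts_cnv` table), `counts` (the counts matrix
#'   with dosage-gene rows rewritten) and `truth` (list with `dosage_genes`,
#'   `coupling`).
#' @export
simulate_cnv <- function(expr, n_dosage_genes, coupling, seed = 1,
                         n_null_genes = 3 * n_dosage_genes) {
  if (coupling <= 0 || coupling > 1) stop("coupling must be in (0, 1]")
  n_total <- n_dosage_genes + n_null_genes
  if (n_total > nrow(expr)) stop("not enough genes in expression matrix")
  set.seed(seed)
  n <- ncol(expr)
  picked <- sample(rownames(expr), n_total)
  dosage <- if (n_dosage_genes > 0) picked[seq_len(n_dosage_genes)] else character(0)
  nulls <- setdiff(picked, dosage)

  amp <- matrix(0, n_total, n, dimnames = list(picked, colnames(expr)))
  counts <- expr
  for (g in dosage) {
    dir <- sample(c(1, -1), 1)
    z_a <- rnorm(n)
    amp[g, ] <- dir * 1 + 0.5 * z_a
    z_e <- coupling * z_a + sqrt(1 - coupling^2) * rnorm(n)
    m <- max(mean(log2(expr[g, ] + 1)), 7)
    counts[g, ] <- monotone_counts(z_e, m, 1.5)
  }
  for (g in nulls) {
    amp[g, ] <- rnorm(n, 0, 0.5)
  }
  info <- data.frame(gene = picked,
                     chrom = sprintf("chr%d", 1 + (seq_len(n_total) - 1) %% 10),
                     q_value = runif(n_total, 0, 0.05),
                     stringsAsFactors = FALSE)
  cnv <- new_cnv_table(info, amp)
  list(cnv = cnv, counts = counts,
       truth = list(dosage_genes = dosage, coupling = coupling, seed = seed))
}

# Dirichlet draws via normalized gammas
rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  x / rowSums(x)
}

#' Default immune cell types for simulation
#' @return Named numeric vector of Dirichlet concentration parameters.
#' @export
default_immune_cell_types <- function() {
  c(B_cells_naive = 4, Macrophages_M2 = 3, Macrophages_M0 = 2.5,
    T_cells_CD8 = 1.5, T_cells_CD4_memory_resting = 1.5,
    Dendritic_cells_resting = 1, Plasma_cells = 0.8,
    Mast_cells_activated = 0.7)
}

#' Simulate immune profiles with CD3-coupled CD8 fractions
#'
#' Cell fractions are Dirichlet-distributed (summing to 1 per sample). The
#' IHC CD3 density is an affine function of the standardized CD8 fraction
#' scaled by the coupling, with multiplicative log-normal noise that
#' vanishes as `|coupling|` approaches 1 (at coupling 1 with zero noise the
#' CD3 density is exactly affine in the CD8 fraction). Mutational burden and
#' binary genomic flags are drawn independently.
#'
#' @param n_samples Number of samples.
#' @param cell_types Named vector of Dirichlet concentrations (must contain
#'   `T_cells_CD8`).
#' @param cd8_cd3_coupling Target CD3/CD8 correlation in `[-1, 1]`.
#' @param seed Integer seed.
#' @param sample_ids Optional sample IDs.
#' @return `data.frame` with `sample_id`, `frac_*` columns, `cd3_density`,
#'   `mut_per_mb`, and binary flags `KMT_MUT`, `TP53_MUT`, `RB1_DEL`.
#' @export
simulate_immune <- function(n_samples, cell_types = default_immune_cell_types(),
                            cd8_cd3_coupling = 0.7, seed = 1,
                            sample_ids = NULL) {
  if (abs(cd8_cd3_coupling) > 1) stop("coupling must be in [-1, 1]")
  if (!"T_cells_CD8" %in% names(cell_types)) {
    stop("cell_types must include 'T_cells_CD8'")
  }
  set.seed(seed)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(n_samples))
  fr <- rdirichlet(n_samples, cell_types)
  colnames(fr) <- paste0("frac_", names(cell_types))
  cd8 <- fr[, "frac_T_cells_CD8"]
  z_cd8 <- as.vector(scale(cd8))
  cc <- cd8_cd3_coupling
  noise <- exp(0.6 * sqrt(1 - cc^2) * rnorm(n_samples))
  cd3 <- pmax(1 + 0.5 * cc * z_cd8, 0.05) * noise
  out <- data.frame(sample_id = sample_ids, fr,
                    cd3_density = cd3,
                    mut_per_mb = rlnorm(n_samples, log(2.7), 0.9),
                    KMT_MUT = rbinom(n_samples, 1, 0.28),
                    TP53_MUT = rbinom(n_samples, 1, 0.21),
                    RB1_DEL = rbinom(n_samples, 1, 0.34),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a MAF-style variant table
#'
#' Variant classes are drawn with frequencies typical of exome cohorts
#' (missense most prevalent), SIFT scores are attached to missense records,
#' and optional planted driver rows are appended verbatim.
#'
#' @param sample_ids Sample identifiers.
#' @param gene_pool Gene symbols to draw from.
#' @param mean_variants Mean variants per sample (Poisson).
#' @param drivers Optional `data.frame` with columns `gene`, `sample_id`,
#'   `variant_class`, `protein_change` (and optionally `sift_score`).
#' @param seed Integer seed.
#' @return MAF `data.frame` in the internal representation (see
#'   [read_maf()]).
#' @export
simulate_maf <- function(sample_ids, gene_pool = sprintf("G%04d", 1:500),
                         mean_variants = 30, drivers = NULL, seed = 1) {
  set.seed(seed)
  class_p <- c(missense = 0.62, frameshift = 0.13, UTR = 0.13,
               nonsense = 0.03, silent = 0.04, splice = 0.02,
               in_frame_indel = 0.01, other = 0.02)
  aa <- c("A", "R", "N", "D", "C", "E", "G", "H", "I", "L", "K", "M", "F",
          "P", "S", "T", "W", "Y", "V")
  rows <- lapply(sample_ids, function(s) {
    n <- rpois(1, mean_variants)
    if (n == 0) return(NULL)
    cls <- sample(names(class_p), n, replace = TRUE, prob = class_p)
    pc <- paste0(sample(aa, n, TRUE), sample(50:900, n, TRUE),
                 ifelse(cls == "frameshift", "Afs*5",
                        ifelse(cls == "nonsense", "*", sample(aa, n, TRUE))))
    data.frame(gene = sample(gene_pool, n, replace = TRUE), sample_id = s,
               variant_class = cls, protein_change = pc,
               sift_score = ifelse(cls == "missense", round(rbeta(n, 0.8, 2), 3),
                                   NA_real_),
               allele_frequency = round(runif(n, 0.05, 0.9), 3),
               stringsAsFactors = FALSE)
  })
  maf <- do.call(rbind, rows)
  if (!is.null(drivers)) {
    if (is.null(drivers$sift_score)) drivers$sift_score <- NA_real_
    if (is.null(drivers$allele_frequency)) drivers$allele_frequency <- 0.4
    maf <- rbind(maf, drivers[, names(maf)])
  }
  rownames(maf) <- NULL
  maf
}

#' Simulate an RNAseq fusion call table
#'
#' Background fusions pair random genes on random chromosomes; a planted
#' oncogenic set (collagen-PDGFB style), same-family pairs, and calls with
#' an unannotated partner exercise every branch of the fusion filter.
#'
#' @param sample_ids Sample identifiers.
#' @param n_background Background (passenger) fusion calls.
#' @param oncogenic_samples Samples to receive a planted COL1A2-PDGFB
#'   fusion (defaults to the first sample).
#' @param seed Integer seed.
#' @return Fusion call `data.frame` (see [read_fusion_calls()]).
#' @export
simulate_fusions <- function(sample_ids, n_background = 20,
                             oncogenic_samples = sample_ids[1], seed = 1) {
  set.seed(seed)
  pool <- c("ABCA1", "BRD4", "CAND2", "DLG1", "EPS15", "FARP1", "GRB2",
            "HERC1", "ITSN1", "JAK2", "KDM5A", "LATS1", "MACF1", "NCOA2",
            "OGT", "PPARG", "QKI", "RREB1", "STAG2", "TPR")
  g5 <- sample(pool, n_background, replace = TRUE)
  g3 <- sample(pool, n_background, replace = TRUE)
  same <- g5 == g3
  g3[same] <- pool[(match(g3[same], pool) %% length(pool)) + 1]
  bg <- data.frame(sample_id = sample(sample_ids, n_background, replace = TRUE),
                   gene5 = g5, gene3 = g3,
                   chrom5 = sprintf("%d", sample(1:38, n_background, TRUE)),
                   chrom3 = sprintf("%d", sample(1:38, n_background, TRUE)),
                   breakpoint5 = sample.int(1e6, n_background),
                   breakpoint3 = sample.int(1e6, n_background),
                   exon5 = sample(1:20, n_background, TRUE),
                   exon3 = sample(1:20, n_background, TRUE),
                   in_frame = sample(c("yes", "no", "unknown"), n_background, TRUE),
                   annotated5 = TRUE, annotated3 = TRUE,
                   stringsAsFactors = FALSE)
  planted <- do.call(rbind, lapply(oncogenic_samples, function(s) {
    data.frame(sample_id = s, gene5 = "COL1A2", gene3 = "PDGFB",
               chrom5 = "14", chrom3 = "26",
               breakpoint5 = 52340, breakpoint3 = 11820,
               exon5 = 6, exon3 = 2, in_frame = "yes",
               annotated5 = TRUE, annotated3 = TRUE,
               stringsAsFactors = FALSE)
  }))
  family_pair <- data.frame(sample_id = sample_ids[1], gene5 = "HBA1",
                            gene3 = "HBA2", chrom5 = "6", chrom3 = "6",
                            breakpoint5 = 1000, breakpoint3 = 8000,
                            exon5 = 1, exon3 = 2, in_frame = "unknown",
                            annotated5 = TRUE, annotated3 = TRUE,
                            stringsAsFactors = FALSE)
  unannot <- data.frame(sample_id = sample_ids[length(sample_ids)],
                        gene5 = "ENSCAFG000001", gene3 = "JAK2",
                        chrom5 = "2", chrom3 = "9",
                        breakpoint5 = 5000, breakpoint3 = 9000,
                        exon5 = NA_integer_, exon3 = 3, in_frame = "unknown",
                        annotated5 = FALSE, annotated3 = TRUE,
                        stringsAsFactors = FALSE)
  out <- rbind(bg, planted, family_pair, unannot)
  rownames(out) <- NULL
  out
}
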