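## One-call generation of a complete synthetic input bundle: every file the
## pipeline consumes, plus a ground-truth JSON.

#' Generate a complete synthetic input bundle on disk
#'
#' Writes, under `dir`: a counts matrix with planted cluster structure (and
#' planted CNV dosage genes and fusion-partner expression), a miniature
#' reference FASTA, per-sample VCFs drawn from reference signature mixtures,
#' a MAF with planted driver variants, a callable-megabase table, a
#' GISTIC-style CNV amplitude table, a fusion call table, an immune profile
#' table, and `truth.json` recording the planted ground truth.
#'
#' The defaults emulate the structure of a 29-tumor cohort: cluster sizes
#' 11/7/5/6, three mutational processes assigned to 15/11/3 samples with at
#' least 200 SNVs each, CNV dosage coupling 0.8, and CD3/CD8 coupling 0.7.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving every generator.
#' @param samples_per_cluster Planted cluster sizes.
#' @param n_genes Genes in the expression matrix.
#' @param markers_per_cluster,lfc Cluster marker structure.
#' @param signature_split Number of samples assigned to each reference
#'   signature (recycled/truncated to the cohort size).
#' @param mutations_per_sample Mean SNVs per sample (minimum 200).
#' @param n_dosage_genes,cnv_coupling Planted CNV dosage structure.
#' @param cd8_cd3_coupling Planted immune coupling.
#' @return Invisibly, a named list of the written paths plus `truth`.
#' @export
simulate_bundle <- function(dir, seed = 1,
                            samples_per_cluster = c(11, 7, 5, 6),
                            n_genes = 2000, markers_per_cluster = 50,
                            lfc = 3, signature_split = c(15, 11, 3),
                            mutations_per_sample = 300,
                            n_dosage_genes = 30, cnv_coupling = 0.8,
                            cd8_cd3_coupling = 0.7) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf_dir <- file.path(dir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)

  expr <- simulate_expression(n_genes, samples_per_cluster,
                              markers_per_cluster, lfc, seed = seed)
  counts <- expr$counts
  samples <- colnames(counts)
  n <- length(samples)

  cnv_sim <- simulate_cnv(counts, n_dosage_genes, cnv_coupling,
                          seed = seed + 1)
  counts <- cnv_sim$counts

  # fusion partner genes with expression inflated in the fused samples
  set.seed(seed + 2)
  fused_samples <- samples[c(12, 13, 16)[c(12, 13, 16) <= n]]
  pdgfb <- rnbinom(n, mu = 120, size = 10)
  pdgfb[samples %in% fused_samples] <- rnbinom(sum(samples %in% fused_samples),
                                               mu = 1500, size = 30)
  col1a2 <- rnbinom(n, mu = 800, size = 10)
  extra <- rbind(PDGFB = pdgfb, COL1A2 = col1a2)
  # MPAS panel genes, expressed with ordinary biological variation
  panel <- t(vapply(mpas_panel(), function(g) {
    rnbinom(n, mu = rlnorm(1, log(200), 0.5), size = 5)
  }, numeric(n)))
  extra <- rbind(extra, panel)
  storage.mode(extra) <- "integer"
  counts <- rbind(counts, extra)

  genome <- generate_genome(3, 100000, 60, seed = seed + 3)
  reference <- read_signature_reference(
    sts_extdata("synthetic_reference_signatures.tsv"))
  K <- ncol(reference$profiles)
  split <- rep(signature_split, length.out = min(length(signature_split), K))
  assigned <- rep(seq_along(split), split)[seq_len(n)]
  if (length(assigned) < n) {
    assigned <- c(assigned, rep(1L, n - length(assigned)))
  }
  set.seed(seed + 4)
  totals <- pmax(round(rlnorm(n, log(mutations_per_sample), 0.2)), 200)
  exposures <- matrix(0, K, n,
                      dimnames = list(colnames(reference$profiles), samples))
  for (j in seq_len(n)) exposures[assigned[j], j] <- totals[j]
  mut <- simulate_mutations(genome, reference, exposures, seed = seed + 5)

  immune <- simulate_immune(n, cd8_cd3_coupling = cd8_cd3_coupling,
                            seed = seed + 6, sample_ids = samples)

  drivers <- data.frame(
    gene = c("TP53", "TP53", "KMT2D", "NF1", "HRAS"),
    sample_id = samples[c(1, 2, 3, 4, 5)],
    variant_class = c("missense", "missense", "nonsense", "frameshift",
                      "missense"),
    protein_change = c("R175H", "R175H", "Q1000*", "A699Ifs*3", "G13R"),
    sift_score = c(0.01, 0.02, NA, NA, 0.0),
    allele_frequency = c(0.45, 0.32, 0.5, 0.1, 0.38),
    stringsAsFactors = FALSE)
  maf <- simulate_maf(samples, gene_pool = rownames(expr$counts)[1:500],
                      mean_variants = 30, drivers = drivers, seed = seed + 7)

  set.seed(seed + 8)
  callable <- data.frame(sample_id = samples,
                         callable_mb = round(runif(n, 8, 12), 2),
                         stringsAsFactors = FALSE)

  fusions <- simulate_fusions(samples, n_background = 20,
                              oncogenic_samples = fused_samples,
                              seed = seed + 9)

  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    fasta = file.path(dir, "genome.fa"),
    vcf_dir = vcf_dir,
    maf = file.path(dir, "variants.maf.tsv"),
    callable_mb = file.path(dir, "callable_mb.tsv"),
    cnv = file.path(dir, "cnv_amplitudes.tsv"),
    fusions = file.path(dir, "fusions.tsv"),
    immune = file.path(dir, "immune_profiles.tsv"),
    truth = file.path(dir, "truth.json"))

  write_counts_matrix(counts, paths$counts)
  write_genome_fasta(genome, paths$fasta)
  for (s in samples) {
    v <- mut$variants[mut$variants$sample_id == s, , drop = FALSE]
    write_vcf(v, file.path(vcf_dir, paste0(s, ".vcf")),
              contig_lengths = nchar(genome$contigs))
  }
  write_maf(maf, paths$maf)
  write.table(callable, paths$callable_mb, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_cnv_table(cnv_sim$cnv, paths$cnv)
  write.table(fusions, paths$fusions, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(immune, paths$immune, sep = "\t", quote = FALSE,
              row.names = FALSE)

  truth <- list(seed = seed,
                cluster_labels = as.list(expr$truth$cluster_labels),
                de_genes = expr$truth$de_genes,
                dosage_genes = cnv_sim$truth$dosage_genes,
                cnv_coupling = cnv_coupling,
                signature_assignment = as.list(setNames(
                  colnames(reference$profiles)[assigned], samples)),
                cd8_cd3_coupling = cd8_cd3_coupling,
                fused_samples = fused_samples)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, list(truth = truth, catalog = mut$catalog)))
}
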