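## Variant-class tallies, tumor mutational burden, recurrently mutated
## genes, SIFT filtering, and putative driver flagging against curated
## cancer-gene / oncogenic-variant references.

#' Tally variant classes per sample and cohort-wide
#'
#' @param maf MAF `data.frame` (see [read_maf()]).
#' @return List with `per_sample` (`data.frame` sample_id x class
#'   fractions; samples with zero variants are absent) and `cohort_median`
#'   (named vector of per-class median fractions across samples).
#' @export
tally_classes <- function(maf) {
  vocab <- variant_class_vocabulary()
  samples <- sort(unique(maf$sample_id))
  frac <- t(vapply(samples, function(s) {
    cls <- maf$variant_class[maf$sample_id == s]
    as.vector(table(factor(cls, levels = vocab)) / length(cls))
  }, numeric(length(vocab))))
  colnames(frac) <- vocab
  per_sample <- data.frame(sample_id = samples, frac,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           row.names = NULL)
  cohort_median <- apply(frac, 2, median)
  list(per_sample = per_sample, cohort_median = cohort_median)
}

#' Coding variant classes counted toward mutational burden
#' @return The non-synonymous coding classes used by [compute_tmb()].
#' @export
tmb_coding_classes <- function() {
  c("missense", "nonsense", "frameshift", "in_frame_indel", "splice")
}

#' Tumor mutational burden per callable megabase
#'
#' Counts non-synonymous coding mutations (classes from
#' [tmb_coding_classes()]) per sample and divides by the sample's callable
#' megabases (genome at coverage > 10X, supplied as input, never
#' recomputed here).
#'
#' @param maf MAF `data.frame`.
#' @param callable_mb Named numeric vector, sample -> callable megabases
#'   (> 0); must cover every sample in `maf`.
#' @param coding_classes Variant classes counted (config list).
#' @return `data.frame` with `sample_id`, `coding_mutations`,
#'   `callable_mb`, `mut_per_mb`.
#' @export
#' @examples
#' maf <- data.frame(gene = "TP53", sample_id = "T1",
#'                   variant_class = "missense", protein_change = "R175H",
#'                   sift_score = 0.01, allele_frequency = 0.4)
#' compute_tmb(maf, c(T1 = 10))
compute_tmb <- function(maf, callable_mb,
                        coding_classes = tmb_coding_classes()) {
  samples <- sort(unique(maf$sample_id))
  missing <- setdiff(samples, names(callable_mb))
  if (length(missing) > 0) {
    stop("callable_mb missing for sample(s): ", paste(missing, collapse = ", "))
  }
  if (any(callable_mb[samples] <= 0)) {
    stop("callable_mb must be > 0 for every sample")
  }
  coding <- maf[maf$variant_class %in% coding_classes, , drop = FALSE]
  n <- table(factor(coding$sample_id, levels = samples))
  data.frame(sample_id = samples,
             coding_mutations = as.integer(n),
             callable_mb = unname(callable_mb[samples]),
             mut_per_mb = as.numeric(n) / unname(callable_mb[samples]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Recurrently mutated genes
#'
#' A gene counts once per sample regardless of how many variants hit it.
#'
#' @param maf MAF `data.frame`.
#' @param n_samples Cohort size used as the denominator.
#' @param min_fraction Minimum fraction of mutated samples for a gene to be
#'   reported (default 0.21). Fractions are compared at display precision
#'   (rounded to two decimals), so 6/29 = 0.207 is reported at the 21%
#'   threshold.
#' @return `data.frame` with `gene`, `n_mutated_samples`, `fraction`,
#'   sorted by descending fraction.
#' @export
recurrent_genes <- function(maf, n_samples, min_fraction = 0.21) {
  stopifnot(n_samples >= 1)
  if (nrow(maf) == 0) {
    return(data.frame(gene = character(0), n_mutated_samples = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  }
  pairs <- unique(maf[, c("gene", "sample_id")])
  n <- sort(table(pairs$gene), decreasing = TRUE)
  out <- data.frame(gene = names(n), n_mutated_samples = as.integer(n),
                    fraction = as.integer(n) / n_samples,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[round(out$fraction, 2) >= round(min_fraction, 2), , drop = FALSE]
}

#' Filter missense variants to SIFT-deleterious calls
#'
#' Retains missense records with `sift_score < threshold` (the standard
#' SIFT deleterious convention). Missense records lacking a score are
#' excluded with a logged count; non-missense records are never passed by
#' this filter.
#'
#' @param maf MAF `data.frame`.
#' @param threshold SIFT deleterious cutoff (default 0.05).
#' @return The retained MAF rows.
#' @export
sift_filter <- function(maf, threshold = 0.05) {
  mis <- maf$variant_class == "missense"
  unscored <- mis & is.na(maf$sift_score)
  if (any(unscored)) {
    sts_log(sum(unscored), " missense record(s) lacked a SIFT score and were excluded",
            stage = "sift")
  }
  out <- maf[mis & !is.na(maf$sift_score) & maf$sift_score < threshold, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load the cancer gene role table
#'
#' @param path TSV with columns `gene`, `role` (oncogene / TSG / both /
#'   unassigned). A packaged synthetic curation is at
#'   `sts_extdata("cancer_genes.tsv")`.
#' @return Named character vector gene -> role.
#' @export
read_cancer_genes <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "role") %in% names(x))) {
    stop("cancer gene table needs columns 'gene' and 'role'")
  }
  bad <- setdiff(unique(x$role), c("oncogene", "TSG", "both", "unassigned"))
  if (length(bad) > 0) stop("unknown gene role(s): ", paste(bad, collapse = ", "))
  setNames(x$role, x$gene)
}

#' Load the oncogenic variant reference table
#'
#' @param path TSV with columns `gene`, `protein_change`, `effect`.
#'   A packaged synthetic curation is at
#'   `sts_extdata("oncogenic_variants.tsv")`.
#' @return `data.frame` of oncogenic / likely-oncogenic variant entries.
#' @export
read_oncogenic_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "protein_change", "effect") %in% names(x))) {
    stop("oncogenic table needs columns gene, protein_change, effect")
  }
  x$protein_change <- sub("^p\\.", "", x$protein_change)
  x
}

#' Load the gene -> biological category map
#'
#' @param path YAML mapping each of the 7 biological categories (cell
#'   cycle / DNA repair; chromatin organization / binding; PI3K-Akt-mTOR;
#'   Wnt; transcription regulator activity; nervous system development;
#'   kinase binding) to a list of gene symbols. A packaged map is at
#'   `sts_extdata("gene_categories.yaml")`.
#' @return Named character vector gene -> category.
#' @export
read_gene_categories <- function(path) {
  y <- yaml::read_yaml(path)
  genes <- unlist(y, use.names = FALSE)
  cats <- rep(names(y), lengths(y))
  if (anyDuplicated(genes)) {
    stop("gene(s) assigned to more than one category: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  setNames(cats, genes)
}

#' Flag putative driver variants
#'
#' A variant is flagged as a putative driver when either
#' (a) its gene is a curated cancer gene and its protein change exactly
#' matches an oncogenic reference entry (evidence `exact_variant_match`), or
#' (b) its gene is a tumor suppressor (role TSG or both) and the variant is
#' truncating (nonsense / frameshift / splice; evidence
#' `truncating_in_TSG`). Protein changes are compared after normalizing
#' away the `p.` prefix; cross-species positional homology mapping is not
#' attempted.
#'
#' @param maf MAF `data.frame`.
#' @param oncogenic_table `data.frame` from [read_oncogenic_table()].
#' @param cancer_genes Named vector from [read_cancer_genes()].
#' @param categories Optional named vector from [read_gene_categories()];
#'   every categorized gene must be a cancer gene.
#' @return `data.frame` of driver calls: `gene`, `sample_id`,
#'   `protein_change`, `variant_class`, `gene_role`, `category`, `evidence`.
#' @export
flag_drivers <- function(maf, oncogenic_table, cancer_genes,
                         categories = NULL) {
  if (!is.null(categories)) {
    orphans <- setdiff(names(categories), names(cancer_genes))
    if (length(orphans) > 0) {
      stop("configuration error: categorized gene(s) absent from cancer ",
           "gene table: ", paste(orphans, collapse = ", "))
    }
  }
  pc <- sub("^p\\.", "", maf$protein_change)
  key <- paste(maf$gene, pc, sep = "|")
  onco_key <- paste(oncogenic_table$gene, oncogenic_table$protein_change,
                    sep = "|")
  in_cancer <- maf$gene %in% names(cancer_genes)
  exact <- in_cancer & key %in% onco_key
  role <- cancer_genes[maf$gene]
  truncating <- in_cancer & role %in% c("TSG", "both") &
    maf$variant_class %in% c("nonsense", "frameshift", "splice")
  hit <- exact | truncating
  out <- data.frame(
    gene = maf$gene[hit],
    sample_id = maf$sample_id[hit],
    protein_change = pc[hit],
    variant_class = maf$variant_class[hit],
    gene_role = unname(role[hit]),
    category = if (is.null(categories)) NA_character_ else
      unname(categories[maf$gene[hit]]),
    evidence = ifelse(exact[hit], "exact_variant_match", "truncating_in_TSG"),
    stringsAsFactors = FALSE)
  out$gene_role[is.na(out$gene_role)] <- "unassigned"
  rownames(out) <- NULL
  out
}
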