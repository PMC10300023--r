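## Readers and writers for the external formats the pipeline consumes:
## patient metadata, counts matrices, VCF, MAF-style variant tables,
## gene-level CNV amplitudes, fusion calls, immune profiles, configs.

#' Read the patient/tumor metadata table
#'
#' Parses a tab-delimited cohort table with one row per tumor and the eight
#' columns `sample_id`, `breed`, `sex`, `age_years`, `subtype`, `location`,
#' `grade`, `cluster`. The packaged cohort fixture
#' (`sts_extdata("patient_table.tsv")`) describes 29 canine soft tissue
#' sarcomas assigned to four expression clusters H1--H4.
#'
#' @param path Path to a TSV file with a header row.
#' @return A `data.frame` with the eight columns, validated: unique
#'   non-empty sample IDs, `sex` in Male/Female, `age_years > 0`, `subtype`
#'   in PNST/FSA/UPS, `grade` in I/II/III, `cluster` in H1--H4.
#' @export
#' @examples
#' pt <- read_patient_table(sts_extdata("patient_table.tsv"))
#' nrow(pt)
#' table(pt$subtype)
read_patient_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(x) == 0) stop("no records in patient table '", path, "'")
  required <- c("sample_id", "breed", "sex", "age_years", "subtype",
                "location", "grade", "cluster")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("patient table missing column(s): ", paste(missing, collapse = ", "))
  }
  x <- x[, required]
  if (anyDuplicated(x$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "))
  }
  chr_cols <- c("sample_id", "breed", "sex", "subtype", "location", "grade",
                "cluster")
  for (cc in chr_cols) {
    if (any(!nzchar(trimws(as.character(x[[cc]]))) | is.na(x[[cc]]))) {
      stop("empty values in field '", cc, "'")
    }
  }
  check_vocab <- function(field, allowed) {
    bad <- setdiff(unique(x[[field]]), allowed)
    if (length(bad) > 0) {
      stop("unknown value(s) in field '", field, "': ",
           paste(bad, collapse = ", "))
    }
  }
  check_vocab("sex", c("Male", "Female"))
  check_vocab("subtype", c("PNST", "FSA", "UPS"))
  check_vocab("grade", c("I", "II", "III"))
  check_vocab("cluster", c("H1", "H2", "H3", "H4"))
  x$age_years <- as.numeric(x$age_years)
  if (any(is.na(x$age_years) | x$age_years <= 0)) {
    stop("field 'age_years' must be a positive number")
  }
  x
}

#' Read / write a gene-by-sample counts matrix
#'
#' The TSV layout is one header row of sample IDs, first column gene IDs,
#' and non-negative integer counts.
#'
#' @param path Path to a TSV file.
#' @return An integer matrix with gene row names and sample column names.
#' @export
read_counts_matrix <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(x) < 2) stop("counts matrix needs a gene column and >=1 sample")
  genes <- as.character(x[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicated gene ID(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  samples <- colnames(x)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicated sample ID(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(is.na(m))) stop("non-numeric entries in counts matrix")
  if (any(m < 0)) stop("negative entries in counts matrix")
  if (any(m != round(m))) stop("non-integer entries in counts matrix")
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' @rdname read_counts_matrix
#' @param counts Integer matrix of counts (genes x samples).
#' @param gene_col Header used for the gene-ID column on write.
#' @export
write_counts_matrix <- function(counts, path, gene_col = "gene_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- gene_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read somatic SNV/INDEL calls from a VCF
#'
#' Keeps only records with `PASS` in the FILTER column (the convention for
#' somatic calls that survived filtering), splits multi-allelic records into
#' one row per ALT allele, and tags every variant with `sample_id`.
#'
#' @param path Path to a VCF v4.2 file.
#' @param sample_id Sample identifier to attach to the returned records.
#' @return A `data.frame` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `sample_id`. Zero-row when the VCF body is empty or nothing
#'   passes the filter.
#' @export
read_vcf <- function(path, sample_id) {
  stopifnot(is.character(sample_id), length(sample_id) == 1)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      sample_id = character(0), stringsAsFactors = FALSE)
  # vcfR errors on a header-only file; treat that as an empty call set
  body_lines <- sum(!startsWith(readLines(path, warn = FALSE), "#"))
  if (body_lines == 0) return(empty)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  keep <- !is.na(fx[, "FILTER"]) & fx[, "FILTER"] == "PASS"
  fx <- fx[keep, , drop = FALSE]
  if (nrow(fx) == 0) return(empty)
  alt_split <- strsplit(fx[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_split)
  out <- data.frame(
    chrom = rep(fx[, "CHROM"], n_alt),
    pos = rep(as.integer(fx[, "POS"]), n_alt),
    ref = rep(fx[, "REF"], n_alt),
    alt = unlist(alt_split, use.names = FALSE),
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  bad <- out$ref == out$alt
  if (any(bad)) stop("malformed record: REF equals ALT at ",
                     out$chrom[bad][1], ":", out$pos[bad][1])
  out
}

#' Write variant records to a minimal VCF v4.2 file
#'
#' @param variants `data.frame` with columns `chrom`, `pos`, `ref`, `alt`
#'   (as returned by [read_vcf()] or [simulate_mutations()]).
#' @param path Output path.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header.
#' @export
write_vcf <- function(variants, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=stsomics")
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", sep = "\t"))
  body <- character(0)
  if (nrow(variants) > 0) {
    ord <- order(variants$chrom, variants$pos)
    v <- variants[ord, ]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                    v$chrom, as.integer(v$pos), v$ref, v$alt)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

# synonym map from MAF-dialect classification strings to the internal
# closed vocabulary
maf_class_synonyms <- function() {
  c(
    "missense_mutation" = "missense",
    "missense" = "missense",
    "frame_shift_del" = "frameshift",
    "frame_shift_ins" = "frameshift",
    "frameshift" = "frameshift",
    "frameshift_variant" = "frameshift",
    "nonsense_mutation" = "nonsense",
    "stop_gained" = "nonsense",
    "nonsense" = "nonsense",
    "3'utr" = "UTR",
    "5'utr" = "UTR",
    "utr" = "UTR",
    "3'flank" = "other",
    "5'flank" = "other",
    "silent" = "silent",
    "synonymous_variant" = "silent",
    "splice_site" = "splice",
    "splice_region" = "splice",
    "splice" = "splice",
    "in_frame_del" = "in_frame_indel",
    "in_frame_ins" = "in_frame_indel",
    "in_frame_indel" = "in_frame_indel",
    "inframe_deletion" = "in_frame_indel",
    "inframe_insertion" = "in_frame_indel",
    "other" = "other"
  )
}

#' The closed variant classification vocabulary
#' @return Character vector of the eight internal variant classes.
#' @export
variant_class_vocabulary <- function() {
  c("missense", "frameshift", "nonsense", "UTR", "silent", "splice",
    "in_frame_indel", "other")
}

#' Read a MAF-style somatic variant table
#'
#' Accepts TCGA-style classification strings (e.g. `Missense_Mutation`,
#' `Frame_Shift_Del`) and common free-text synonyms via a documented synonym
#' map; anything unrecognized is mapped to class `"other"` with a warning,
#' never dropped. SIFT scores are parsed either from a numeric column or
#' from annotations of the form `"deleterious(0.01)"`, and are retained only
#' for missense records.
#'
#' @param path Path to a tab-delimited file with columns `Hugo_Symbol`,
#'   `Tumor_Sample_Barcode`, `Variant_Classification`, `HGVSp_Short`; a
#'   `SIFT` column and an `allele_frequency` (or `t_AF`) column are optional.
#' @return A `data.frame` with columns `gene`, `sample_id`, `variant_class`,
#'   `protein_change`, `sift_score`, `allele_frequency`.
#' @export
read_maf <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  comment.char = "#")
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode",
                "Variant_Classification", "HGVSp_Short")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("MAF missing required column(s): ", paste(missing, collapse = ", "))
  }
  syn <- maf_class_synonyms()
  raw_class <- tolower(trimws(x$Variant_Classification))
  cls <- unname(syn[raw_class])
  unknown <- is.na(cls)
  if (any(unknown)) {
    warning("unrecognized variant classification(s) mapped to 'other': ",
            paste(unique(x$Variant_Classification[unknown]), collapse = ", "))
    cls[unknown] <- "other"
  }
  parse_sift <- function(s) {
    if (is.numeric(s)) return(as.numeric(s))
    s <- as.character(s)
    num <- suppressWarnings(as.numeric(s))
    inpar <- sub(".*\\(([0-9.eE+-]+)\\).*", "\\1", s)
    num2 <- suppressWarnings(as.numeric(inpar))
    ifelse(!is.na(num), num, num2)
  }
  sift <- if ("SIFT" %in% names(x)) parse_sift(x$SIFT) else rep(NA_real_, nrow(x))
  sift[cls != "missense"] <- NA_real_
  af_col <- intersect(c("allele_frequency", "t_AF", "tumor_f"), names(x))
  af <- if (length(af_col) > 0) as.numeric(x[[af_col[1]]]) else rep(NA_real_, nrow(x))
  protein <- sub("^p\\.", "", as.character(x$HGVSp_Short))
  data.frame(
    gene = as.character(x$Hugo_Symbol),
    sample_id = as.character(x$Tumor_Sample_Barcode),
    variant_class = cls,
    protein_change = protein,
    sift_score = sift,
    allele_frequency = af,
    stringsAsFactors = FALSE
  )
}

#' @rdname read_maf
#' @param maf `data.frame` in the internal MAF representation.
#' @export
write_maf <- function(maf, path) {
  back <- c(missense = "Missense_Mutation", frameshift = "Frame_Shift_Del",
            nonsense = "Nonsense_Mutation", UTR = "3'UTR", silent = "Silent",
            splice = "Splice_Site", in_frame_indel = "In_Frame_Del",
            other = "Other")
  out <- data.frame(
    Hugo_Symbol = maf$gene,
    Tumor_Sample_Barcode = maf$sample_id,
    Variant_Classification = unname(back[maf$variant_class]),
    HGVSp_Short = ifelse(nzchar(maf$protein_change),
                         paste0("p.", maf$protein_change), ""),
    SIFT = maf$sift_score,
    allele_frequency = maf$allele_frequency,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene-level CNV amplitude table
#'
#' GISTIC-style layout: columns `gene`, `chrom`, `q_value`, then one signed
#' amplitude column per sample. Per-gene direction (AMP/DEL) is derived from
#' the sign of the cohort-median amplitude. Amplitude units (log2 ratio or
#' copy-number difference) are not interpreted; downstream correlation is
#' unit-invariant.
#'
#' @param path Path to a TSV file.
#' @return An object of class `sts_cnv`: a list with `info` (`data.frame`
#'   gene/chrom/q_value/direction) and `amplitudes` (genes x samples matrix).
#' @export
read_cnv_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("gene", "chrom", "q_value")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("CNV table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(x$gene)) {
    stop("duplicated gene in CNV table: ",
         paste(unique(x$gene[duplicated(x$gene)]), collapse = ", "))
  }
  amp <- as.matrix(x[, setdiff(names(x), required), drop = FALSE])
  storage.mode(amp) <- "double"
  rownames(amp) <- x$gene
  new_cnv_table(info = x[, required], amplitudes = amp)
}

new_cnv_table <- function(info, amplitudes) {
  med <- apply(amplitudes, 1, median)
  info$direction <- ifelse(med >= 0, "AMP", "DEL")
  structure(list(info = info, amplitudes = amplitudes), class = "sts_cnv")
}

#' @rdname read_cnv_table
#' @param cnv An `sts_cnv` object.
#' @export
write_cnv_table <- function(cnv, path) {
  df <- data.frame(cnv$info[, c("gene", "chrom", "q_value")],
                   cnv$amplitudes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.sts_cnv <- function(x, ...) {
  cat("Gene-level CNV amplitude table\n")
  cat("  genes:  ", nrow(x$amplitudes), "\n")
  cat("  samples:", ncol(x$amplitudes), "\n")
  cat("  AMP/DEL:", sum(x$info$direction == "AMP"), "/",
      sum(x$info$direction == "DEL"), "\n")
  invisible(x)
}

#' Read a fusion call table
#'
#' @param path TSV with columns `sample_id`, `gene5`, `gene3`, `chrom5`,
#'   `chrom3`, `breakpoint5`, `breakpoint3`; optional `exon5`, `exon3`,
#'   `in_frame` (yes/no/unknown), `annotated5`, `annotated3` (logical).
#' @return A `data.frame` of fusion calls with the optional columns filled
#'   with defaults (`in_frame = "unknown"`, `annotated* = TRUE`).
#' @export
read_fusion_calls <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "gene5", "gene3", "chrom5", "chrom3",
                "breakpoint5", "breakpoint3")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("fusion table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!"exon5" %in% names(x)) x$exon5 <- NA_integer_
  if (!"exon3" %in% names(x)) x$exon3 <- NA_integer_
  if (!"in_frame" %in% names(x)) x$in_frame <- "unknown"
  if (!"annotated5" %in% names(x)) x$annotated5 <- TRUE
  if (!"annotated3" %in% names(x)) x$annotated3 <- TRUE
  x$annotated5 <- as.logical(x$annotated5)
  x$annotated3 <- as.logical(x$annotated3)
  if (any(x$breakpoint5 < 1 | x$breakpoint3 < 1)) {
    stop("fusion breakpoints must be >= 1 (1-based)")
  }
  x
}

#' Read an immune profile table
#'
#' One row per sample: deconvolved cell-type fractions (columns prefixed
#' `frac_`), an IHC CD3 density column `cd3_density`, mutational burden
#' `mut_per_mb`, and binary genomic flag columns (e.g. `KMT_MUT`).
#'
#' @param path TSV path.
#' @param check_fractions Verify the `frac_` columns sum to 1 per sample
#'   (within 1e-6).
#' @return A `data.frame` with `sample_id` first.
#' @export
read_immune_profiles <- function(path, check_fractions = TRUE) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(x)) stop("immune table missing 'sample_id'")
  if (anyDuplicated(x$sample_id)) stop("duplicate sample_id in immune table")
  frac_cols <- grep("^frac_", names(x), value = TRUE)
  if (check_fractions && length(frac_cols) > 0) {
    s <- rowSums(x[, frac_cols, drop = FALSE])
    if (any(abs(s - 1) > 1e-6)) {
      stop("cell fractions do not sum to 1 for sample(s): ",
           paste(x$sample_id[abs(s - 1) > 1e-6], collapse = ", "))
    }
  }
  x
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' @param path Path ending in `.yaml`/`.yml` or `.json`.
#' @return A named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json, got '", ext, "'")
  }
}
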