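## Fusion classification, driver filtering and partner expression
## concordance.

#' Classify fusions as inter- or intrachromosomal
#'
#' A fusion is intrachromosomal when both partners lie on the same
#' chromosome. The summary deduplicates calls by
#' `(gene5, gene3, sample_id)`, so repeated call rows for one fusion count
#' once.
#'
#' @param calls Fusion call `data.frame` (see [read_fusion_calls()]).
#' @return The calls with a `type` column added; the deduplicated summary
#'   counts (`total`, `interchromosomal`, `intrachromosomal`) are attached
#'   as attribute `"summary"`.
#' @export
classify_fusions <- function(calls) {
  calls$type <- ifelse(calls$chrom5 == calls$chrom3,
                       "intrachromosomal", "interchromosomal")
  uniq <- !duplicated(calls[, c("gene5", "gene3", "sample_id")])
  attr(calls, "summary") <- c(
    total = sum(uniq),
    interchromosomal = sum(uniq & calls$type == "interchromosomal"),
    intrachromosomal = sum(uniq & calls$type == "intrachromosomal"))
  calls
}

# gene family root: strip trailing digits from the symbol
# (COL1A1, COL1A2 -> COL1A; HBA1, HBA2 -> HBA). An approximation used only
# when no curated family map is supplied.
default_family_root <- function(symbol) {
  sub("[0-9]+$", "", symbol)
}

#' Load a gene -> family map
#'
#' @param path TSV with columns `gene`, `family`.
#' @return Named character vector gene -> family.
#' @export
read_family_map <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "family") %in% names(x))) {
    stop("family map needs columns 'gene' and 'family'")
  }
  setNames(x$family, x$gene)
}

#' Load the oncogenic fusion-partner reference list
#'
#' @param path TSV with columns `gene`, `role` (oncogene / TSG). A packaged
#'   synthetic list is at `sts_extdata("oncogenic_fusion_partners.tsv")`.
#' @return Named character vector gene -> role.
#' @export
read_oncogenic_partners <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "role") %in% names(x))) {
    stop("oncogenic partner list needs columns 'gene' and 'role'")
  }
  setNames(x$role, x$gene)
}

#' Filter fusion calls to putative oncogenic drivers
#'
#' Applies three commuting filters: self-fusions and partners from the same
#' gene family are dropped (`same_family`); calls with an unannotated
#' partner are dropped (`unannotated`); and only calls with at least one
#' partner in the oncogenic reference list (oncogene activation or TSG
#' loss) are retained (`no_oncogenic_partner` otherwise).
#'
#' @param calls Fusion call `data.frame`.
#' @param oncogenic_partners Named vector gene -> role (see
#'   [read_oncogenic_partners()]).
#' @param family_map Optional named vector gene -> family; when absent,
#'   families are approximated by the trailing-digit-stripped symbol root.
#' @return The retained calls. The full table with per-call `eliminated`
#'   reasons is attached as attribute `"audit"`.
#' @export
filter_fusions <- function(calls, oncogenic_partners, family_map = NULL) {
  fam <- function(g) {
    if (is.null(family_map)) return(default_family_root(g))
    out <- unname(family_map[g])
    miss <- is.na(out)
    out[miss] <- default_family_root(g[miss])
    out
  }
  reason <- rep(NA_character_, nrow(calls))
  same_family <- calls$gene5 == calls$gene3 |
    (fam(calls$gene5) == fam(calls$gene3) & nzchar(fam(calls$gene5)))
  reason[same_family] <- "same_family"
  unannot <- !calls$annotated5 | !calls$annotated3
  reason[is.na(reason) & unannot] <- "unannotated"
  onco <- calls$gene5 %in% names(oncogenic_partners) |
    calls$gene3 %in% names(oncogenic_partners)
  reason[is.na(reason) & !onco] <- "no_oncogenic_partner"
  audit <- calls
  audit$eliminated <- reason
  kept <- calls[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "audit") <- audit
  kept
}

#' Expression concordance of retained fusion partners
#'
#' For each retained fusion, reports the fused sample's z-scored expression
#' of the oncogenic partner: an oncogene partner is expected up
#' (`z > 0`), a TSG partner is expected down (`z < 0`); `concordant` is
#' whether the observed sign matches. Partners absent from the expression
#' matrix are reported with status `"untested"`.
#'
#' @param calls Retained fusion calls (from [filter_fusions()]).
#' @param z Z matrix from [zscore_expression()].
#' @param oncogenic_partners Named vector gene -> role.
#' @return `data.frame` with `sample_id`, `gene`, `partner_role`,
#'   `z_score`, `direction_expected`, `concordant`, `status`.
#' @export
fusion_expression_concordance <- function(calls, z, oncogenic_partners) {
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    for (g in c(calls$gene5[i], calls$gene3[i])) {
      if (!g %in% names(oncogenic_partners)) next
      role <- unname(oncogenic_partners[g])
      expected <- if (role == "oncogene") "up" else "down"
      s <- calls$sample_id[i]
      if (g %in% rownames(z) && s %in% colnames(z)) {
        zs <- z[g, s]
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, gene = g, partner_role = role, z_score = zs,
          direction_expected = expected,
          concordant = (expected == "up" & zs > 0) |
            (expected == "down" & zs < 0),
          status = "tested", stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, gene = g, partner_role = role, z_score = NA_real_,
          direction_expected = expected, concordant = NA,
          status = "untested", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(sample_id = character(0), gene = character(0),
                      partner_role = character(0), z_score = numeric(0),
                      direction_expected = character(0),
                      concordant = logical(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
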