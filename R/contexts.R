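#' Canonical 96 trinucleotide mutation contexts
#'
#' The 96 single-base-substitution contexts in the canonical COSMIC order:
#' the six pyrimidine-strand substitution classes (C>A, C>G, C>T, T>A, T>C,
#' T>G) in blocks, and within each block the 16 flanking-base pairs in
#' alphabetical order (5' base varying slowest). Labels have the form
#' `"A[C>T]G"`.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(trinucleotide_contexts())
trinucleotide_contexts <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (cls in substitution_classes()) {
    for (p5 in bases) {
      for (p3 in bases) {
        out <- c(out, paste0(p5, "[", cls, "]", p3))
      }
    }
  }
  out
}

#' The six pyrimidine-strand substitution classes
#'
#' @return Character vector `c("C>A","C>G","C>T","T>A","T>C","T>G")`.
#' @export
substitution_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

# reverse complement of a plain A/C/G/T string (vectorized)
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# map (ref, alt, 5' base, 3' base) on the reference strand to the
# pyrimidine-strand context label; purine refs are reverse-complemented
snv_context <- function(ref, alt, p5, p3) {
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, chartr("ACGT", "TGCA", ref), ref)
  a <- ifelse(pur, chartr("ACGT", "TGCA", alt), alt)
  l5 <- ifelse(pur, chartr("ACGT", "TGCA", p3), p5)
  l3 <- ifelse(pur, chartr("ACGT", "TGCA", p5), p3)
  paste0(l5, "[", r, ">", a, "]", l3)
}

#' Cosine similarity between two non-negative profiles
#'
#' @param a,b Numeric vectors of equal length, non-negative, not all zero.
#' @return `sum(a*b) / (||a|| * ||b||)`, a value in `[0, 1]` for non-negative
#'   inputs.
#' @export
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 1)) # 0.5
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must have equal length")
  if (any(a < 0) || any(b < 0)) stop("profiles must be non-negative")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

# column-wise cosine similarity matrix between two non-negative matrices
cosine_matrix <- function(A, B) {
  An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  Bn <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  M <- crossprod(An, Bn)
  rownames(M) <- colnames(A); colnames(M) <- colnames(B)
  M
}
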