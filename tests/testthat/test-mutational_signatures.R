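test_that("context labels follow the canonical order", {
  ctx <- trinucleotide_contexts()
  expect_length(ctx, 96)
  expect_equal(ctx[1], "A[C>A]A")
  expect_equal(ctx[17], "A[C>G]A")
  expect_equal(ctx[96], "T[T>G]T")
  expect_equal(unique(substr(ctx, 3, 5)), substitution_classes())
  expect_false(anyDuplicated(ctx) > 0)
})

test_that("catalog assigns pyrimidine and purine substitutions to one context", {
  #        123456789
  seq <- c(c1 = "TACGTTGCA")
  gen <- tiny_genome(seq)
  vars <- data.frame(
    chrom = "c1",
    pos = c(3L, 7L),
    ref = c("C", "G"),     # G>A at 5'T..3'C -> revcomp context G[C>T]A
    alt = c("T", "A"),
    sample_id = "S1", stringsAsFactors = FALSE)
  cata <- build_catalog(vars, gen)
  expect_equal(unname(cata["A[C>T]G", "S1"]), 1L)
  expect_equal(unname(cata["G[C>T]A", "S1"]), 1L)  # revcomp of TGC is GCA
  expect_equal(sum(cata), 2)
})

test_that("catalog ignores indels, rejects edge positions and ref mismatches", {
  gen <- tiny_genome(c(c1 = "TACGTTGCA"))
  withindel <- data.frame(chrom = "c1", pos = c(3L, 5L),
                          ref = c("C", "TT"), alt = c("T", "T"),
                          sample_id = "S1", stringsAsFactors = FALSE)
  expect_message(cata <- build_catalog(withindel, gen), "ignored")
  expect_equal(sum(cata), 1)
  expect_equal(attr(cata, "n_indels_ignored"), 1)

  edge <- data.frame(chrom = "c1", pos = 1L, ref = "T", alt = "A",
                     sample_id = "S1", stringsAsFactors = FALSE)
  expect_error(build_catalog(edge, gen), "edge")
  mism <- data.frame(chrom = "c1", pos = 3L, ref = "G", alt = "A",
                     sample_id = "S1", stringsAsFactors = FALSE)
  expect_error(build_catalog(mism, gen), "mismatches")
  badctg <- data.frame(chrom = "c9", pos = 3L, ref = "C", alt = "T",
                       sample_id = "S1", stringsAsFactors = FALSE)
  expect_error(build_catalog(badctg, gen), "absent")
})

test_that("catalog is invariant under reverse-complementing the assembly", {
  gen <- generate_genome(1, 20000, 0, seed = 3)
  ref <- read_signature_reference(sts_extdata("synthetic_reference_signatures.tsv"))
  expo <- matrix(c(120, 0, 80, 0, 0), 5, 1,
                 dimnames = list(ref$names, "S1"))
  mut <- simulate_mutations(gen, ref, expo, seed = 2)
  cata <- build_catalog(mut$variants, gen)

  L <- nchar(gen$contigs[[1]])
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", gen$contigs[[1]]),
                           "")[[1]]), collapse = "")
  gen_rc <- tiny_genome(setNames(rc, names(gen$contigs)))
  vars_rc <- mut$variants
  vars_rc$pos <- L - vars_rc$pos + 1L
  vars_rc$ref <- chartr("ACGT", "TGCA", vars_rc$ref)
  vars_rc$alt <- chartr("ACGT", "TGCA", vars_rc$alt)
  cata_rc <- build_catalog(vars_rc, gen_rc)
  expect_equal(cata_rc, cata, ignore_attr = TRUE)
})

test_that("collapse to 6 substitution classes conserves counts", {
  gen <- generate_genome(1, 30000, 0, seed = 9)
  ref <- read_signature_reference(sts_extdata("synthetic_reference_signatures.tsv"))
  expo <- matrix(c(100, 100, 100, 0, 0), 5, 1,
                 dimnames = list(ref$names, "S1"))
  mut <- simulate_mutations(gen, ref, expo, seed = 4)
  cata <- build_catalog(mut$variants, gen)
  six <- collapse_classes(cata)
  expect_equal(rownames(six), substitution_classes())
  expect_equal(colSums(six), colSums(cata))
})

test_that("cosine similarity matches hand values and rejects zero vectors", {
  expect_equal(cosine_similarity(c(1, 2, 2, 0), 2 * c(1, 2, 2, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(c(1, -1), c(1, 1)), "non-negative")
})

test_that("KL-NMF recovers an exact rank-3 factorization", {
  ref <- read_signature_reference(sts_extdata("synthetic_reference_signatures.tsv"))
  W0 <- ref$profiles[, c("SBS5_synth", "SBS6_synth", "SBS29_synth")]
  # well-separated regime: each sample dominated by one signature
  set.seed(31)
  H0 <- matrix(rlnorm(3 * 12, log(30), 0.3), 3, 12)
  for (j in 1:12) H0[(j - 1) %% 3 + 1, j] <- H0[(j - 1) %% 3 + 1, j] + 400
  V <- W0 %*% H0
  colnames(V) <- sprintf("S%02d", 1:12)
  sigs <- extract_signatures(V, rank = 3, n_restarts = 8, max_iter = 2000,
                             seed = 7)
  best <- apply(cosine_matrix_oracle(sigs$profiles, W0), 2, max)
  expect_true(all(best >= 0.99))
  # objective is non-increasing across iterations
  expect_true(all(diff(sigs$objective_trace) <= 1e-6))
})

test_that("a single-signature sample pair is recovered at rank 1", {
  ref <- read_signature_reference(sts_extdata("synthetic_reference_signatures.tsv"))
  W0 <- ref$profiles[, "SBS6_synth", drop = FALSE]
  cata <- catalog_from_profiles(W0, c(1, 1), c(10000, 10000), seed = 5)
  sigs <- extract_signatures(cata, rank = 1, n_restarts = 3, max_iter = 1000,
                             seed = 2)
  expect_gte(cosine_similarity(sigs$profiles[, 1], W0[, 1]), 0.99)
})

test_that("NMF is deterministic given seed and restart count", {
  ref <- read_signature_reference(sts_extdata("synthetic_reference_signatures.tsv"))
  cata <- catalog_from_profiles(ref$profiles[, 1:2], c(1, 2, 1, 2),
                                rep(300, 4), seed = 8)
  a <- extract_signatures(cata, rank = 2, n_restarts = 4, max_iter = 500,
                          seed = 3)
  b <- extract_signatures(cata, rank = 2, n_restarts = 4, max_iter = 500,
                          seed = 3)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$exposures, b$exposures)
  # profiles are probability vectors
  expect_equal(unname(colSums(a$profiles)), rep(1, 2), tolerance = 1e-9)
  expect_error(extract_signatures(cata, rank = 4), "rank")
})

test_that("rank-range selection picks the planted rank", {
  ref <- read_signature_reference(sts_extdata("synthetic_reference_signatures.tsv"))
  W0 <- ref$profiles[, c("SBS5_synth", "SBS6_synth", "SBS29_synth")]
  cata <- catalog_from_profiles(W0, rep(1:3, each = 6), rep(500, 18), seed = 4)
  sigs <- extract_signatures(cata, rank = 2:5, n_restarts = 4, max_iter = 800,
                             seed = 11)
  expect_equal(ncol(sigs$profiles), 3)
  expect_s3_class(sigs$rank_metrics, "data.frame")
})

test_that("naming and per-sample assignment use argmax cosine", {
  ref <- read_signature_reference(sts_extdata("synthetic_reference_signatures.tsv"))
  denovo <- structure(list(profiles = ref$profiles[, c(2, 3)],
                           exposures = NULL, names = c("A", "B")),
                      class = "sts_signatures")
  colnames(denovo$profiles) <- c("A", "B")
  assigned <- c(2, 3, 2)
  cata <- catalog_from_profiles(ref$profiles, assigned, rep(5000, 3), seed = 6)
  res <- name_and_assign(denovo, ref, cata)
  expect_equal(res$naming$name, c("SBS6_synth-like", "SBS29_synth-like"))
  expect_equal(res$naming$cosine, c(1, 1), tolerance = 1e-12)
  expect_equal(res$assignment$signature, colnames(ref$profiles)[assigned])
  expect_true(all(res$sample_cosine >= 0 & res$sample_cosine <= 1 + 1e-12))
  empty_ref <- structure(list(profiles = NULL), class = "sts_signatures")
  expect_error(name_and_assign(denovo, empty_ref, cata), "empty reference")
})

test_that("signature reference loader validates and renormalizes", {
  ref <- read_signature_reference(sts_extdata("synthetic_reference_signatures.tsv"))
  expect_equal(nrow(ref$profiles), 96)
  expect_equal(unname(colSums(ref$profiles)), rep(1, ncol(ref$profiles)),
               tolerance = 1e-9)
  f <- tempfile(fileext = ".tsv")
  write_signature_reference(ref, f)
  back <- read_signature_reference(f)
  expect_equal(back$profiles, ref$profiles, tolerance = 1e-9)
  bad <- write_lines_tmp(c("context\tX", "A[C>A]A\t1"), ".tsv")
  expect_error(read_signature_reference(bad), "96")
})
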