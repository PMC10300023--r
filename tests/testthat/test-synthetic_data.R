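test_that("genome generation is deterministic, feasible genes, errors otherwise", {
  g1 <- generate_genome(1, 10000, 5, seed = 1)
  g2 <- generate_genome(1, 10000, 5, seed = 1)
  expect_identical(g1, g2)
  expect_equal(sum(nchar(g1$contigs)), 10000)
  expect_equal(nrow(g1$genes), 5)
  # genes within bounds and non-overlapping
  gn <- g1$genes[order(g1$genes$start), ]
  expect_true(all(gn$start >= 1 & gn$end <= nchar(g1$contigs[gn$contig])))
  expect_true(all(diff(gn$start) > 0))
  expect_true(all(head(gn$end, -1) < gn$start[-1]))
  expect_error(generate_genome(1, 10000, 1e6, seed = 1), "cannot place")
  g3 <- generate_genome(1, 10000, 5, seed = 2)
  expect_false(identical(g1$contigs, g3$contigs))
})

test_that("genome FASTA round-trips through Biostrings", {
  g <- generate_genome(2, 4000, 0, seed = 4)
  f <- tempfile(fileext = ".fa")
  write_genome_fasta(g, f)
  back <- read_genome_fasta(f)
  expect_identical(back$contigs, g$contigs)
})

test_that("expression simulation has the requested shape and determinism", {
  sim <- simulate_expression(300, c(11, 7, 5, 6), 20, lfc = 2, seed = 5)
  expect_equal(dim(sim$counts), c(300L, 29L))
  expect_equal(unname(table(sim$truth$cluster_labels)), c(11, 7, 5, 6),
               ignore_attr = TRUE)
  sim2 <- simulate_expression(300, c(11, 7, 5, 6), 20, lfc = 2, seed = 5)
  expect_identical(sim$counts, sim2$counts)
  expect_error(simulate_expression(300, c(10), 20, lfc = 2, seed = 1),
               "2 clusters")
  # planted markers really are elevated in their own cluster
  norm <- median_ratio_normalize(sim$counts)
  k1 <- sim$truth$cluster_labels == 1
  mk <- sim$truth$de_genes$cluster1
  lfc_obs <- rowMeans(norm$log2[mk, k1]) - rowMeans(norm$log2[mk, !k1])
  expect_gt(median(lfc_obs), 1.5)
})

test_that("lfc = 0 plants no recoverable structure", {
  sim <- simulate_expression(400, c(6, 6, 6), 30, lfc = 0, seed = 11)
  cl <- cluster_samples(median_ratio_normalize(sim$counts)$log2, k = 3)
  expect_lt(ari(cl$labels, sim$truth$cluster_labels), 0.3)
})

test_that("a single-context signature yields only that substitution at matching sites", {
  gen <- generate_genome(1, 50000, 0, seed = 2)
  W <- matrix(0, 96, 1, dimnames = list(trinucleotide_contexts(), "pure"))
  W["A[C>T]G", 1] <- 1
  expo <- matrix(50, 1, 1, dimnames = list("pure", "S1"))
  mut <- simulate_mutations(gen, W, expo, seed = 3)
  expect_equal(nrow(mut$variants), 50)
  expect_true(all(paste(mut$variants$ref, mut$variants$alt) %in%
                    c("C T", "G A")))
  seq <- gen$contigs[[1]]
  for (i in seq_len(nrow(mut$variants))) {
    p <- mut$variants$pos[i]
    trip <- substr(seq, p - 1, p + 1)
    if (mut$variants$ref[i] == "C") expect_equal(trip, "ACG")
    else expect_equal(trip, "CGT")  # reverse complement placement
  }
  expect_equal(sum(mut$catalog), 50)
  expect_equal(unname(mut$catalog["A[C>T]G", 1]), 50L)
})

test_that("zero exposures give no variants; catalog round-trip is exact", {
  gen <- generate_genome(2, 60000, 0, seed = 7)
  ref <- read_signature_reference(sts_extdata("synthetic_reference_signatures.tsv"))
  expo0 <- matrix(0, 5, 2,
                  dimnames = list(ref$names, c("S1", "S2")))
  mut0 <- simulate_mutations(gen, ref, expo0, seed = 1)
  expect_equal(nrow(mut0$variants), 0)

  for (s in 1:3) {
    expo <- matrix(rlnorm(10, log(150), 0.3), 5, 2,
                   dimnames = list(ref$names, c("S1", "S2")))
    mut <- simulate_mutations(gen, ref, expo, seed = s)
    cata <- build_catalog(mut$variants, gen)
    expect_equal(unname(cata), unname(mut$catalog[, colnames(cata)]),
                 ignore_attr = TRUE)
    expect_equal(sum(cata), nrow(mut$variants))
  }
})

test_that("CNV coupling 1 makes amplitudes rank-identical to expression", {
  sim <- simulate_expression(200, c(10, 10), 10, lfc = 1, seed = 9)
  cs <- simulate_cnv(sim$counts, 20, coupling = 1, seed = 2)
  for (g in cs$truth$dosage_genes) {
    expect_equal(rank(cs$cnv$amplitudes[g, ]), rank(cs$counts[g, ]),
                 ignore_attr = TRUE)
  }
})

test_that("CNV coupling is recovered within tolerance at n = 60", {
  sim <- simulate_expression(300, c(30, 30), 10, lfc = 1, seed = 13)
  cs <- simulate_cnv(sim$counts, 40, coupling = 0.7, seed = 3)
  z <- zscore_expression(median_ratio_normalize(cs$counts))
  r <- vapply(cs$truth$dosage_genes, function(g) {
    cor(cs$cnv$amplitudes[g, ], z[g, ])
  }, numeric(1))
  expect_lt(abs(mean(r) - 0.7), 0.15)
  expect_error(simulate_cnv(sim$counts, 10, coupling = 0, seed = 1),
               "coupling")
})

test_that("immune fractions are Dirichlet-normalized and CD3 coupling behaves", {
  im <- simulate_immune(40, cd8_cd3_coupling = 0.7, seed = 21)
  fr <- as.matrix(im[, grep("^frac_", names(im))])
  expect_equal(unname(rowSums(fr)), rep(1, 40), tolerance = 1e-9)
  expect_true(all(im$cd3_density >= 0))

  # coupling 1 has zero noise: exactly affine in the CD8 fraction
  im1 <- simulate_immune(25, cd8_cd3_coupling = 1, seed = 5)
  r1 <- cor(im1$cd3_density, im1$frac_T_cells_CD8)
  expect_equal(r1, 1, tolerance = 1e-12)

  expect_error(simulate_immune(10, cd8_cd3_coupling = 1.5, seed = 1),
               "coupling")
})

test_that("null CD3 coupling is rarely significant", {
  sig <- vapply(1:30, function(s) {
    im <- simulate_immune(29, cd8_cd3_coupling = 0, seed = 100 + s)
    cor.test(im$cd3_density, im$frac_T_cells_CD8)$p.value < 0.05
  }, logical(1))
  expect_lte(mean(sig), 0.2)
})

test_that("MAF simulation plants drivers verbatim and round-trips", {
  drv <- data.frame(gene = "TP53", sample_id = "S01",
                    variant_class = "missense", protein_change = "R175H",
                    stringsAsFactors = FALSE)
  maf <- simulate_maf(sprintf("S%02d", 1:4), mean_variants = 15,
                      drivers = drv, seed = 2)
  expect_true(any(maf$gene == "TP53" & maf$protein_change == "R175H"))
  expect_true(all(is.na(maf$sift_score[maf$variant_class != "missense"])))
  f <- tempfile(fileext = ".tsv")
  write_maf(maf, f)
  expect_equal(nrow(read_maf(f)), nrow(maf))
})

test_that("fusion simulation covers every filter branch", {
  fus <- simulate_fusions(sprintf("S%02d", 1:5), seed = 3)
  expect_true(any(fus$gene5 == "COL1A2" & fus$gene3 == "PDGFB"))
  expect_true(any(fus$gene5 == "HBA1" & fus$gene3 == "HBA2"))
  expect_true(any(!fus$annotated5 | !fus$annotated3))
  expect_true(all(fus$breakpoint5 >= 1 & fus$breakpoint3 >= 1))
})
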