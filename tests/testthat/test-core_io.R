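test_that("packaged patient table parses and matches the cohort composition", {
  pt <- read_patient_table(sts_extdata("patient_table.tsv"))
  expect_equal(nrow(pt), 29)
  expect_equal(sum(pt$subtype == "PNST"), 14)
  expect_equal(sum(pt$subtype == "FSA"), 14)
  expect_equal(sum(pt$subtype == "UPS"), 1)
  expect_equal(unname(table(pt$cluster)[c("H1", "H2", "H3", "H4")]),
               c(11, 7, 5, 6), ignore_attr = TRUE)
  expect_false(anyDuplicated(pt$sample_id) > 0)
  expect_true(all(pt$age_years > 0))
})

test_that("patient table parser rejects malformed inputs with named fields", {
  f <- write_lines_tmp("sample_id\tbreed\tsex\tage_years\tsubtype\tlocation\tgrade\tcluster")
  expect_error(read_patient_table(f), "no records")

  pt <- read.delim(sts_extdata("patient_table.tsv"))
  f2 <- tempfile(fileext = ".tsv")
  write.table(pt[, -2], f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_patient_table(f2), "breed")

  dup <- rbind(pt, pt[1, ])
  f3 <- tempfile(fileext = ".tsv")
  write.table(dup, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_patient_table(f3), "duplicate sample_id.*T1860")

  bad <- pt; bad$sex[3] <- "F"
  f4 <- tempfile(fileext = ".tsv")
  write.table(bad, f4, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_patient_table(f4), "sex")
})

test_that("counts matrix round-trips exactly and rejects bad entries", {
  f <- write_lines_tmp(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t0\t5", "g3\t7\t0"),
                       ".tsv")
  m <- read_counts_matrix(f)
  expect_equal(dim(m), c(3L, 2L))
  expect_identical(m["g2", "s2"], 5L)

  f2 <- tempfile(fileext = ".tsv")
  write_counts_matrix(m, f2)
  expect_identical(read_counts_matrix(f2), m)

  fdup <- write_lines_tmp(c("gene_id\ts1", "g1\t1", "g1\t2"), ".tsv")
  expect_error(read_counts_matrix(fdup), "g1")
  fneg <- write_lines_tmp(c("gene_id\ts1", "g1\t-1"), ".tsv")
  expect_error(read_counts_matrix(fneg), "negative")
  ffrac <- write_lines_tmp(c("gene_id\ts1", "g1\t1.5"), ".tsv")
  expect_error(read_counts_matrix(ffrac), "non-integer")
})

vcf_header <- c("##fileformat=VCFv4.2",
                "##contig=<ID=chr1,length=1000>",
                "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")

test_that("VCF reader keeps PASS records only and splits multi-allelics", {
  f <- write_lines_tmp(c(vcf_header,
                         "chr1\t5\t.\tC\tT\t.\tPASS\t.",
                         "chr1\t10\t.\tG\tA\t.\tgermline_risk\t.",
                         "chr1\t20\t.\tA\tC,G\t.\tPASS\t."), ".vcf")
  v <- read_vcf(f, "T1")
  expect_equal(nrow(v), 3)  # 1 biallelic PASS + 2 from the multi-allelic
  expect_equal(v$pos[v$ref == "C"], 5)
  expect_equal(v$alt[v$ref == "C"], "T")
  expect_setequal(v$alt[v$pos == 20], c("C", "G"))
  expect_true(all(v$sample_id == "T1"))
})

test_that("VCF reader returns an empty frame for an empty body", {
  f <- write_lines_tmp(vcf_header, ".vcf")
  v <- read_vcf(f, "T1")
  expect_equal(nrow(v), 0)
  expect_named(v, c("chrom", "pos", "ref", "alt", "sample_id"))
})

test_that("VCF writer and reader round-trip variant records", {
  vars <- data.frame(chrom = c("chr1", "chr1"), pos = c(5L, 9L),
                     ref = c("C", "G"), alt = c("T", "A"),
                     sample_id = "T2", stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".vcf")
  write_vcf(vars, f, contig_lengths = c(chr1 = 1000))
  back <- read_vcf(f, "T2")
  expect_equal(back[order(back$pos), ], vars[order(vars$pos), ],
               ignore_attr = TRUE)
})

test_that("MAF reader normalizes classes and parses SIFT; unknowns warn", {
  f <- write_lines_tmp(c(
    "Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification\tHGVSp_Short\tSIFT",
    "TP53\tT1\tMissense_Mutation\tp.R175H\tdeleterious(0.01)",
    "NF1\tT1\tFrame_Shift_Del\tp.A699Ifs*3\t",
    "KMT2D\tT2\tNonsense_Mutation\tp.Q100*\t",
    "ODD1\tT2\tWeird\tp.X1Y\t0.5"), ".maf.tsv")
  expect_warning(maf <- read_maf(f), "Weird")
  expect_equal(nrow(maf), 4)  # no row silently dropped
  expect_equal(maf$variant_class,
               c("missense", "frameshift", "nonsense", "other"))
  expect_equal(maf$sift_score[1], 0.01)
  expect_true(is.na(maf$sift_score[2]))  # SIFT only kept for missense
  expect_equal(maf$protein_change[1], "R175H")
  expect_true(all(maf$variant_class %in% variant_class_vocabulary()))
})

test_that("MAF writer round-trips through the reader", {
  maf <- data.frame(gene = c("TP53", "NF1"), sample_id = c("T1", "T2"),
                    variant_class = c("missense", "frameshift"),
                    protein_change = c("R175H", "A699Ifs*3"),
                    sift_score = c(0.01, NA), allele_frequency = c(0.4, 0.1),
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_maf(maf, f)
  expect_equal(read_maf(f), maf, ignore_attr = TRUE)
})

test_that("CNV table reader derives direction from the median amplitude", {
  f <- write_lines_tmp(c("gene\tchrom\tq_value\ts1\ts2\ts3",
                         "A\tchr1\t0.01\t1\t2\t0.5",
                         "B\tchr2\t0.02\t-1\t-0.5\t-2"), ".tsv")
  cnv <- read_cnv_table(f)
  expect_s3_class(cnv, "sts_cnv")
  expect_equal(cnv$info$direction, c("AMP", "DEL"))
  f2 <- tempfile(fileext = ".tsv")
  write_cnv_table(cnv, f2)
  cnv2 <- read_cnv_table(f2)
  expect_equal(cnv2$amplitudes, cnv$amplitudes)
})

test_that("immune profile reader validates fraction sums", {
  f <- write_lines_tmp(c("sample_id\tfrac_a\tfrac_b\tcd3_density",
                         "S1\t0.4\t0.6\t1.2",
                         "S2\t0.3\t0.6\t0.8"), ".tsv")
  expect_error(read_immune_profiles(f), "S2")
  ok <- read_immune_profiles(f, check_fractions = FALSE)
  expect_equal(nrow(ok), 2)
})

test_that("config reader handles YAML and JSON", {
  fy <- write_lines_tmp(c("counts: a.tsv", "seed: 3"), ".yaml")
  cfg <- read_config(fy)
  expect_equal(cfg$seed, 3)
  fj <- write_lines_tmp('{"counts": "a.tsv", "seed": 3}', ".json")
  expect_equal(read_config(fj)$seed, 3)
  expect_error(read_config("x.txt"), "yaml")
})
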