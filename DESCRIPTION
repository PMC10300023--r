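Package: stsomics
Title: Integrated Transcriptomic, Genomic and Immunogenomic Profiling of
    Canine Soft Tissue Sarcomas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable implementation of a multi-omics
    characterization workflow for canine soft tissue sarcoma cohorts:
    median-of-ratios count normalization, variance-based gene filtering and
    Spearman/Ward.D2 hierarchical clustering with elbow selection of the
    cluster number, 96-trinucleotide-context mutation catalogs with de novo
    signature extraction by Kullback-Leibler non-negative matrix
    factorization and cosine-similarity naming against reference
    single-base-substitution signatures, tumor mutational burden and driver
    variant summarization, copy-number dosage-effect screening, gene fusion
    filtering, MAPK pathway activity (MPAS) scoring, and immune infiltrate
    correlation analysis. A synthetic-data module generates every input the
    pipeline consumes with known ground truth, so each stage is verifiable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    yaml,
    jsonlite,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
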