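## End-to-end pipeline orchestration: a single validated config drives all
## stages, each stage communicates with the next only through files in the
## run directory, and an integrated sample-by-feature table joins the
## results.

default_thresholds <- function() {
  list(mean_min = 2, var_min = 5, lfc_min = 2, q_max = 0.05,
       sift_max = 0.05, recurrence_min = 0.21)
}

#' Validate a pipeline run configuration
#'
#' Checks that every referenced input file exists and that thresholds are
#' within their documented ranges, before any stage runs.
#'
#' @param config Named list (typically from [read_config()]): input paths
#'   (`counts`, and optionally `fasta` + `vcf_dir`, `maf`, `callable_mb`,
#'   `cnv`, `fusions`, `immune`, `reference_signatures`, `cancer_genes`,
#'   `oncogenic_table`, `categories`, `oncogenic_partners`, `family_map`),
#'   `out_dir`, `seed`, optional `thresholds` overrides, optional `stages`
#'   character vector, optional `signature_rank`.
#' @return The validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.null(config$counts)) stop("config error: 'counts' path is required")
  if (is.null(config$out_dir)) stop("config error: 'out_dir' is required")
  path_keys <- c("counts", "fasta", "maf", "callable_mb", "cnv", "fusions",
                 "immune", "reference_signatures", "cancer_genes",
                 "oncogenic_table", "categories", "oncogenic_partners",
                 "family_map")
  for (key in path_keys) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      stop("config error: '", key, "' path does not exist: ", config[[key]])
    }
  }
  if (!is.null(config$vcf_dir) && !dir.exists(config$vcf_dir)) {
    stop("config error: 'vcf_dir' does not exist: ", config$vcf_dir)
  }
  th <- modifyList(default_thresholds(), config$thresholds %||% list())
  rng <- list(mean_min = c(0, Inf), var_min = c(0, Inf), lfc_min = c(0, Inf),
              q_max = c(0, 1), sift_max = c(0, 1), recurrence_min = c(0, 1))
  for (nm in names(rng)) {
    if (th[[nm]] < rng[[nm]][1] || th[[nm]] > rng[[nm]][2]) {
      stop("config error: threshold '", nm, "' out of range")
    }
  }
  config$thresholds <- th
  config$seed <- as.integer(config$seed %||% 1L)
  config$signature_rank <- config$signature_rank %||% 3L
  config$stages <- config$stages %||%
    c("cluster", "signatures", "variants", "cnv", "fusions", "immune")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order (cluster, signatures, variants,
#' cnv, fusions, immune), writing each stage's tables under
#' `config$out_dir` and finally an integrated long table with one row per
#' (sample, feature). Stage outputs are pure functions of (inputs, config,
#' seed); a failing stage aborts with the stage name while earlier outputs
#' are preserved on disk.
#'
#' @param config Run configuration (see [validate_config()]); a path to a
#'   YAML/JSON config file is also accepted.
#' @return Invisibly, a list of in-memory stage results plus
#'   `integrated`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  log_path <- file.path(out, "run.log")
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), paste0(...), "\n",
        file = log_path, append = TRUE)
  }
  cfg_hash <- substr(jsonlite::base64_enc(serialize(
    config[order(names(config))], NULL)), 1, 16)
  log_line("stsomics ", as.character(utils::packageVersion("stsomics")),
           " | seed ", config$seed, " | config hash ", cfg_hash)

  run_stage <- function(name, fn) {
    log_line("stage ", name, " start")
    res <- tryCatch(fn(), error = function(e) {
      log_line("stage ", name, " FAILED: ", conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_line("stage ", name, " done")
    res
  }

  results <- list()
  counts <- read_counts_matrix(config$counts)
  norm <- median_ratio_normalize(counts)
  zmat <- zscore_expression(norm)

  if ("cluster" %in% config$stages) {
    results$cluster <- run_stage("cluster", function() {
      genes <- filter_variable_genes(norm, th$mean_min, th$var_min)
      if (length(genes) < 2) stop("variable-gene filter retained < 2 genes")
      cl <- cluster_samples(norm$log2[genes, , drop = FALSE], k = "auto")
      mds <- mds_coordinates(cl$distance)
      write_tsv(data.frame(sample_id = names(cl$labels),
                           cluster = paste0("C", cl$labels)),
                file.path(out, "cluster_labels.tsv"))
      write_tsv(data.frame(k = as.integer(names(cl$wss_curve)),
                           wss = unname(cl$wss_curve)),
                file.path(out, "wss_curve.tsv"))
      write_tsv(data.frame(sample_id = rownames(mds), mds),
                file.path(out, "mds.tsv"))
      de <- lapply(sort(unique(cl$labels)), function(k) {
        hits <- de_screen(norm, cl$labels, k, th$lfc_min, th$q_max)
        write_tsv(hits, file.path(out, sprintf("de_cluster%d.tsv", k)))
        hits
      })
      list(clustering = cl, n_variable_genes = length(genes), de = de)
    })
  }

  if ("signatures" %in% config$stages &&
      (!is.null(config$vcf_dir) || !is.null(config$catalog))) {
    results$signatures <- run_stage("signatures", function() {
      catalog <- if (!is.null(config$catalog)) {
        as.matrix(read.delim(config$catalog, row.names = 1, check.names = FALSE))
      } else {
        vcfs <- dir(config$vcf_dir, pattern = "\\.vcf$", full.names = TRUE)
        if (length(vcfs) == 0) stop("no VCFs in vcf_dir")
        variants <- do.call(rbind, lapply(vcfs, function(f) {
          read_vcf(f, sample_id = sub("\\.vcf$", "", basename(f)))
        }))
        build_catalog(variants, config$fasta)
      }
      write_tsv(data.frame(context = rownames(catalog), catalog,
                           check.names = FALSE),
                file.path(out, "catalog.tsv"))
      sigs <- extract_signatures(catalog, rank = config$signature_rank,
                                 n_restarts = config$nmf_restarts %||% 20,
                                 max_iter = config$nmf_max_iter %||% 1000,
                                 seed = config$seed)
      write_signature_reference(sigs, file.path(out, "denovo_signatures.tsv"))
      write_tsv(data.frame(signature = rownames(sigs$exposures),
                           sigs$exposures, check.names = FALSE),
                file.path(out, "exposures.tsv"))
      assign <- NULL
      if (!is.null(config$reference_signatures)) {
        ref <- read_signature_reference(config$reference_signatures)
        assign <- name_and_assign(sigs, ref, catalog)
        write_tsv(assign$naming, file.path(out, "signature_naming.tsv"))
        write_tsv(assign$assignment, file.path(out, "sample_assignment.tsv"))
        write_tsv(data.frame(sample = rownames(assign$sample_cosine),
                             assign$sample_cosine, check.names = FALSE),
                  file.path(out, "sample_cosine.tsv"))
      }
      list(catalog = catalog, signatures = sigs, assignment = assign)
    })
  }

  if ("variants" %in% config$stages && !is.null(config$maf)) {
    results$variants <- run_stage("variants", function() {
      maf <- read_maf(config$maf)
      tallies <- tally_classes(maf)
      write_tsv(tallies$per_sample, file.path(out, "class_fractions.tsv"))
      tmb <- NULL
      if (!is.null(config$callable_mb)) {
        cm <- read.delim(config$callable_mb, stringsAsFactors = FALSE)
        tmb <- compute_tmb(maf, setNames(cm$callable_mb, cm$sample_id))
        write_tsv(tmb, file.path(out, "tmb.tsv"))
      }
      rec <- recurrent_genes(maf, length(unique(maf$sample_id)),
                             th$recurrence_min)
      write_tsv(rec, file.path(out, "recurrent_genes.tsv"))
      deleterious <- sift_filter(maf, th$sift_max)
      write_tsv(deleterious, file.path(out, "sift_deleterious.tsv"))
      drivers <- NULL
      if (!is.null(config$cancer_genes) && !is.null(config$oncogenic_table)) {
        cg <- read_cancer_genes(config$cancer_genes)
        ot <- read_oncogenic_table(config$oncogenic_table)
        cats <- if (!is.null(config$categories))
          read_gene_categories(config$categories) else NULL
        drivers <- flag_drivers(maf, ot, cg, cats)
        write_tsv(drivers, file.path(out, "drivers.tsv"))
      }
      list(maf = maf, tallies = tallies, tmb = tmb, recurrent = rec,
           deleterious = deleterious, drivers = drivers)
    })
  }

  if ("cnv" %in% config$stages && !is.null(config$cnv)) {
    results$cnv <- run_stage("cnv", function() {
      cnv <- read_cnv_table(config$cnv)
      dosage <- correlate_cnv_expression(cnv, zmat, th$q_max)
      write_tsv(dosage, file.path(out, "cnv_dosage.tsv"))
      imb <- amp_del_imbalance(cnv)
      jsonlite::write_json(imb[c("prop_amplified", "statistic", "p", "method")],
                           file.path(out, "cnv_imbalance.json"),
                           auto_unbox = TRUE, digits = NA)
      list(cnv = cnv, dosage = dosage, imbalance = imb)
    })
  }

  if ("fusions" %in% config$stages && !is.null(config$fusions)) {
    results$fusions <- run_stage("fusions", function() {
      calls <- classify_fusions(read_fusion_calls(config$fusions))
      partners <- if (!is.null(config$oncogenic_partners)) {
        read_oncogenic_partners(config$oncogenic_partners)
      } else {
        read_oncogenic_partners(sts_extdata("oncogenic_fusion_partners.tsv"))
      }
      fam <- if (!is.null(config$family_map))
        read_family_map(config$family_map) else NULL
      kept <- filter_fusions(calls, partners, fam)
      write_tsv(attr(kept, "audit"), file.path(out, "fusions_audit.tsv"))
      conc <- fusion_expression_concordance(kept, zmat, partners)
      write_tsv(conc, file.path(out, "fusion_concordance.tsv"))
      list(calls = calls, kept = kept, concordance = conc,
           summary = attr(calls, "summary"))
    })
  }

  if ("immune" %in% config$stages && !is.null(config$immune)) {
    results$immune <- run_stage("immune", function() {
      prof <- read_immune_profiles(config$immune)
      mpas <- tryCatch(mpas_score(zmat), error = function(e) NULL)
      if (!is.null(mpas)) {
        prof$mpas <- unname(mpas[prof$sample_id])
        write_tsv(data.frame(sample_id = names(mpas), mpas = unname(mpas)),
                  file.path(out, "mpas.tsv"))
      }
      cm <- immune_correlation_matrix(prof, th$q_max)
      write_tsv(data.frame(variable = rownames(cm$r), cm$r,
                           check.names = FALSE),
                file.path(out, "immune_correlation_r.tsv"))
      write_tsv(data.frame(variable = rownames(cm$q), cm$q,
                           check.names = FALSE),
                file.path(out, "immune_correlation_q.tsv"))
      ct <- NULL
      if (!is.null(results$cluster)) {
        cd3 <- setNames(prof$cd3_density, prof$sample_id)
        ct <- cd3_cluster_test(cd3, results$cluster$clustering$labels)
        jsonlite::write_json(list(statistic = ct$statistic, p = ct$p),
                             file.path(out, "cd3_cluster_test.json"),
                             auto_unbox = TRUE, digits = NA)
        screen <- cd3_gene_screen(zmat, cd3, th$q_max)
        write_tsv(screen$table, file.path(out, "cd3_gene_screen.tsv"))
      }
      list(profiles = prof, correlation = cm, cd3_test = ct)
    })
  }

  results$integrated <- run_stage("integrate", function() {
    rows <- list()
    add <- function(sample, type, feature, value) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sample, feature_type = type, feature = feature,
        value = as.character(value), stringsAsFactors = FALSE)
    }
    if (!is.null(results$cluster)) {
      lab <- results$cluster$clustering$labels
      for (s in names(lab)) add(s, "cluster", "expression_cluster",
                                paste0("C", lab[[s]]))
    }
    if (!is.null(results$signatures) && !is.null(results$signatures$assignment)) {
      a <- results$signatures$assignment$assignment
      for (i in seq_len(nrow(a))) {
        add(a$sample[i], "signature", a$signature[i],
            sprintf("%.3f", a$cosine[i]))
      }
    }
    if (!is.null(results$variants) && !is.null(results$variants$drivers)) {
      d <- results$variants$drivers
      for (i in seq_len(nrow(d))) {
        add(d$sample_id[i], "driver", d$gene[i], d$protein_change[i])
      }
    }
    if (!is.null(results$cnv)) {
      pass <- results$cnv$dosage[results$cnv$dosage$passes, , drop = FALSE]
      for (i in seq_len(nrow(pass))) {
        for (s in colnames(results$cnv$cnv$amplitudes)) {
          a <- results$cnv$cnv$amplitudes[pass$gene[i], s]
          if (abs(a) > 0.5) {
            add(s, "CNV", pass$gene[i], if (a > 0) "AMP" else "DEL")
          }
        }
      }
    }
    if (!is.null(results$fusions)) {
      k <- results$fusions$kept
      for (i in seq_len(nrow(k))) {
        add(k$sample_id[i], "fusion",
            paste0(k$gene5[i], "-", k$gene3[i]), k$type[i])
      }
    }
    if (!is.null(results$immune)) {
      prof <- results$immune$profiles
      if (!is.null(prof$mpas)) {
        for (i in seq_len(nrow(prof))) {
          add(prof$sample_id[i], "MPAS", "mpas",
              sprintf("%.4f", prof$mpas[i]))
        }
      }
      for (i in seq_len(nrow(prof))) {
        add(prof$sample_id[i], "immune", "cd3_density",
            sprintf("%.4f", prof$cd3_density[i]))
      }
    }
    tbl <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(sample_id = character(0), feature_type = character(0),
                 feature = character(0), value = character(0))
    tbl <- tbl[order(tbl$sample_id, tbl$feature_type, tbl$feature), ]
    rownames(tbl) <- NULL
    write_tsv(tbl, file.path(out, "integrated_features.tsv"))
    tbl
  })

  log_line("pipeline complete")
  invisible(results)
}
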