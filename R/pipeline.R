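#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end pipeline with its
#' default: the simulator configuration, the extraction filters (minimum
#' usable reads 200, secondary-allele fraction 0.10), the rarity
#' threshold (2), the lineage significance level (0.001), the
#' differential-expression thresholds (adjusted P 0.01, log2 fold change
#' 1), the UMI space (4096) and the global seed. Unknown keys are
#' rejected so configuration typos fail loudly, and a configuration
#' round-trips through YAML unchanged.
#'
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "extract", "cooccur", "lineage", "signatures")`.
#' @param sim named list of [sim_config()] overrides.
#' @param null logical; simulate the exchangeable null cohort instead of
#'   the fate-biased cohort.
#' @param extract list: `n_cells`, `reads_per_cell`, `error_rate` for the
#'   FASTQ round-trip demonstration stage.
#' @param rare_threshold rarity threshold for co-occurrence.
#' @param alpha adjusted-P significance threshold for lineage calls.
#' @param min_reads,allele_frac single-cell allele-calling filters.
#' @param de_max_p_adj,de_min_log2_fc gene-set inclusion thresholds.
#' @param umi_space UMI tag space size.
#' @param seed global seed; stage substreams derive from it.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(stages = c("simulate", "cooccur", "lineage", "signatures"),
                            sim = list(), null = FALSE,
                            extract = list(n_cells = 48, reads_per_cell = 300,
                                           error_rate = 0),
                            rare_threshold = 2, alpha = 0.001,
                            min_reads = 200, allele_frac = 0.10,
                            de_max_p_adj = 0.01, de_min_log2_fc = 1,
                            umi_space = 4096, seed = 1L) {
  known <- c("simulate", "extract", "cooccur", "lineage", "signatures")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop_invalid("unknown stage(s): %s", paste(bad, collapse = ", "))
  }
  bad_sim <- setdiff(names(sim), names(formals(sim_config)))
  if (length(bad_sim)) {
    stop_invalid("unknown sim key(s): %s", paste(bad_sim, collapse = ", "))
  }
  structure(list(stages = stages, sim = sim, null = isTRUE(null),
                 extract = extract,
                 rare_threshold = rare_threshold, alpha = alpha,
                 min_reads = min_reads, allele_frac = allele_frac,
                 de_max_p_adj = de_max_p_adj, de_min_log2_fc = de_min_log2_fc,
                 umi_space = umi_space, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Unknown keys in the file are rejected.
#'
#' @param path YAML path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop_validation("unknown configuration key(s): %s", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the pipeline end to end
#'
#' Executes the toggled stages (simulate, optional FASTQ extraction
#' round trip, rare-barcode co-occurrence, binomial lineage inference,
#' gene-signature scoring) into a run directory and writes a provenance
#' manifest (configuration, seed, package version, per-stage row counts).
#' Reruns with the same configuration and seed reproduce identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) {
    stop_invalid("config must be a pipeline_config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("clonescar")),
                   seed = config$seed, null = config$null,
                   config = unclass(config), stages = list())
  stage_error <- function(stage, e) {
    stop(errorCondition(sprintf("[%s] %s", stage, conditionMessage(e)),
                        class = c("clonescar_stage_error", "error")))
  }

  cohort <- NULL
  if ("simulate" %in% config$stages) {
    tryCatch({
      sc_args <- config$sim
      sc_args$seed <- sc_args$seed %||% config$seed
      cfg <- do.call(sim_config, sc_args)
      cohort <- if (config$null) simulate_null_cohort(cfg) else simulate_cohort(cfg)
      write_barcode_table(cohort$bulk,
                          file.path(out_dir, "bulk_counts.tsv"),
                          file.path(out_dir, "bulk_samples.tsv"))
      write_sim_truth(cohort$truth, file.path(out_dir, "truth.json"))
      for (m in names(cohort$sc)) {
        write_clone_table(cohort$sc[[m]]$clones,
                          file.path(out_dir, sprintf("clones_%s.tsv", m)))
        if (!is.null(cohort$sc[[m]]$counts)) {
          write_count_matrix(cohort$sc[[m]]$counts,
                             file.path(out_dir, sprintf("counts_%s", m)))
        }
      }
      manifest$stages$simulate <- list(
        n_barcodes = nrow(cohort$bulk$counts),
        n_samples = ncol(cohort$bulk$counts),
        n_sc_datasets = length(cohort$sc))
    }, error = function(e) stage_error("simulate", e))
  } else {
    cpath <- file.path(out_dir, "bulk_counts.tsv")
    if (!file.exists(cpath)) {
      stop(errorCondition(
        sprintf("no prior simulate output in '%s': enable the simulate stage or point the run at an existing directory", out_dir),
        class = c("clonescar_stage_error", "error")))
    }
    cohort <- list(
      bulk = read_barcode_table(cpath,
                                file.path(out_dir, "bulk_samples.tsv")),
      sc = NULL)
    clone_files <- list.files(out_dir, "^clones_m[0-9]+\\.tsv$", full.names = TRUE)
    if (length(clone_files)) {
      cohort$sc <- lapply(clone_files, function(f) list(clones = read_clone_table(f)))
      names(cohort$sc) <- sub("^clones_(m[0-9]+)\\.tsv$", "\\1", basename(clone_files))
    }
  }

  if ("extract" %in% config$stages) {
    tryCatch({
      if (is.null(cohort$sc) || !length(cohort$sc)) {
        stop("no single-cell dataset available for extraction")
      }
      clones <- utils::head(cohort$sc[[1]]$clones, config$extract$n_cells)
      fq <- synthesize_fastq(clones,
                             reads_per_cell = config$extract$reads_per_cell,
                             error_rate = config$extract$error_rate,
                             seed = config$seed,
                             left = file.path(out_dir, "reads_1.fastq.gz"),
                             right = file.path(out_dir, "reads_2.fastq.gz"))
      parsed <- parse_read_pairs(read_fastq(fq$left), read_fastq(fq$right))
      calls <- call_cell_scars(parsed, sex = "male",
                               min_reads = config$min_reads,
                               allele_frac = config$allele_frac)
      calls$cell_id <- fq$cells$cell_id[match(calls$cell_barcode,
                                              fq$cells$cell_barcode)]
      utils::write.table(calls, file.path(out_dir, "cell_scar_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$extract <- list(n_cells = nrow(calls),
                                      n_pass = sum(calls$status == "pass"))
    }, error = function(e) stage_error("extract", e))
  }

  if ("cooccur" %in% config$stages) {
    tryCatch({
      sets <- rare_barcode_sets(cohort$bulk, config$rare_threshold)
      P <- cooccurrence_matrix(sets)
      utils::write.table(data.frame(sample = rownames(P), P, check.names = FALSE),
                         file.path(out_dir, "cooccurrence_P.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      em <- enrichment_values(cohort$bulk, config$rare_threshold)
      utils::write.table(em, file.path(out_dir, "enrichment_Em.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$cooccur <- list(n_samples = nrow(P),
                                      n_mice = nrow(em),
                                      mean_Em = mean(em$E_m[is.finite(em$E_m)]))
    }, error = function(e) stage_error("cooccur", e))
  }

  if ("lineage" %in% config$stages) {
    tryCatch({
      if (is.null(cohort$sc) || !length(cohort$sc)) {
        stop("no single-cell clone tables available")
      }
      bg <- background_frequency(cohort$bulk)
      n_sig <- 0
      for (m in names(cohort$sc)) {
        calls <- suppressWarnings(
          barcode_population_tests(cohort$sc[[m]]$clones, bg,
                                   alpha = config$alpha))
        utils::write.table(calls,
                           file.path(out_dir, sprintf("lineage_calls_%s.tsv", m)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        pat <- classify_barcode_patterns(calls)
        utils::write.table(pat,
                           file.path(out_dir, sprintf("lineage_patterns_%s.tsv", m)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        n_sig <- n_sig + sum(calls$significant)
      }
      manifest$stages$lineage <- list(n_datasets = length(cohort$sc),
                                      n_significant = n_sig)
    }, error = function(e) stage_error("lineage", e))
  }

  if ("signatures" %in% config$stages) {
    tryCatch({
      mats <- list()
      for (m in names(cohort$sc) %||% character(0)) {
        d <- file.path(out_dir, sprintf("counts_%s", m))
        if (!is.null(cohort$sc[[m]]$counts)) {
          mats[[m]] <- cohort$sc[[m]]$counts
        } else if (dir.exists(d)) {
          mats[[m]] <- read_count_matrix(d)
        }
      }
      if (!length(mats)) stop("no count matrices available")
      ref <- names(mats)[1]
      cl <- cohort$sc[[ref]]$clones
      clusters <- stats::setNames(cl$population, cl$cell_id)
      sets <- derive_gene_sets(mats[[ref]], clusters,
                               cluster_map = list(EP = "EP", PP = "PP",
                                                  cTEC = "cTEC", mTEC = "mTEC"),
                               max_p_adj = config$de_max_p_adj,
                               min_log2_fc = config$de_min_log2_fc)
      set_df <- data.frame(gene = unlist(sets, use.names = FALSE),
                           set = rep(names(sets), lengths(sets)))
      utils::write.table(set_df, file.path(out_dir, "gene_sets.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      all_scores <- NULL
      for (m in names(mats)) {
        sc <- score_cells(mats[[m]], sets)
        sc$dataset <- m
        sc$cluster <- cohort$sc[[m]]$clones$population[
          match(sc$cell, cohort$sc[[m]]$clones$cell_id)]
        all_scores <- rbind(all_scores, sc)
      }
      utils::write.table(all_scores, file.path(out_dir, "cell_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      coords <- cluster_ratio_coordinates(all_scores, all_scores$cluster,
                                          all_scores$dataset, reference = ref)
      utils::write.table(coords, file.path(out_dir, "cluster_coordinates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$signatures <- list(set_sizes = lengths(sets),
                                         n_clusters = nrow(coords))
    }, error = function(e) stage_error("signatures", e))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
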