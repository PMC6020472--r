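# End-to-end orchestration: generate (or load) inputs, run every stage
# with deterministic seeds, and write per-stage TSV outputs plus a run
# manifest.  The stage functions are thin compositions of the exported
# module functions, so the pipeline adds no statistics of its own.

#' Default pipeline configuration
#'
#' Every threshold used by the analysis surfaces here as a named key
#' with its conventional default: 0.05 FDR for splicing and expression,
#' a 5% inclusion-level difference, Spearman rho 0.7, a 0.5 recurrence
#' fraction, and a twofold abundance change.
#'
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @return Nested named list of stage configurations.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    expression = list(n_datasets = 3, genes_total = 2000,
                      planted_size = 100, planted_delta = -1,
                      samples_per_group = 3, noise_sd = 1),
    meta = list(wilkinson_r = 1, alpha = 0.05, min_datasets = NULL),
    splicing = list(n_samples = 18, fdr_max = 0.05, min_abs_diff = 0.05,
                    min_fraction = 0.5),
    timecluster = list(c = 3, m = 2, min_membership = 0.5),
    network = list(n_datasets = 4, rho_min = 0.7, alpha = 0.05,
                   window = 2000),
    overlap = list(fold = 2)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Validate a pipeline configuration
#'
#' @param config Nested list as from [default_pipeline_config()].
#' @return The validated config, invisibly; errors name the offending
#'   field (condition class `splicemeta_config_error`).
#' @export
validate_pipeline_config <- function(config) {
  fail <- function(field, msg) {
    stop(structure(class = c("splicemeta_config_error", "error",
                             "condition"),
                   list(message = paste0("config field '", field, "': ",
                                         msg),
                        call = sys.call(-1))))
  }
  if (!is.numeric(config$seed)) fail("seed", "must be an integer")
  e <- config$expression
  if (e$planted_size > e$genes_total)
    fail("expression.planted_size", "exceeds genes_total")
  if (e$samples_per_group < 2)
    fail("expression.samples_per_group", "must be >= 2")
  m <- config$meta
  if (m$wilkinson_r < 1 || m$wilkinson_r > e$n_datasets)
    fail("meta.wilkinson_r",
         paste0("must lie in 1..n_datasets (", e$n_datasets, ")"))
  if (m$alpha <= 0 || m$alpha >= 1) fail("meta.alpha", "must be in (0,1)")
  s <- config$splicing
  if (s$min_fraction < 0 || s$min_fraction > 1)
    fail("splicing.min_fraction", "must be in [0,1]")
  tc <- config$timecluster
  if (tc$c < 2) fail("timecluster.c", "must be >= 2")
  if (tc$m <= 1) fail("timecluster.m", "must be > 1")
  nw <- config$network
  if (nw$rho_min < -1 || nw$rho_min > 1)
    fail("network.rho_min", "must be in [-1,1]")
  if (config$overlap$fold < 1) fail("overlap.fold", "must be >= 1")
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to [default_pipeline_config()] values.
#'
#' @param path YAML file path.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- .merge_config(default_pipeline_config(), user)
  validate_pipeline_config(config)
  config
}

#' Run the full pipeline on the synthetic study conditions
#'
#' Executes every stage with deterministic seeds derived from the master
#' seed: expression simulation, quantile renormalization, per-dataset
#' moderated differential expression, Wilkinson meta-analysis with the
#' exclusive-direction filter, pathway enrichment of the
#' significant-consistent genes, splicing-table simulation, significance
#' filtering, recurrence counting and type summary, the retained-intron
#' stop scan, fuzzy c-means time clustering with trend labels, the TF
#' co-regulation network, and set-overlap summaries.  Each stage writes
#' a TSV under `out_dir` and a single `manifest.json` records the
#' configuration and output checksums.
#'
#' @param config A config list (see [default_pipeline_config()]), a YAML
#'   path, or `NULL` for the defaults.
#' @param out_dir Output directory (created; must not already contain a
#'   manifest from a different run unless `overwrite = TRUE`).
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir, overwrite = TRUE) {
  if (is.null(config)) config <- default_pipeline_config()
  if (is.character(config)) config <- read_pipeline_config(config)
  else {
    config <- .merge_config(default_pipeline_config(), config)
    validate_pipeline_config(config)
  }
  if (dir.exists(out_dir) && !overwrite &&
      length(list.files(out_dir)) > 0)
    stop("output directory not empty: ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  paths <- character(0)
  save_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <<- c(paths, p)
    p
  }

  ## expression -> DE -> meta -> enrichment
  e <- config$expression
  sim <- gen_expression_multiset(
    seed, n_datasets = e$n_datasets, genes_total = e$genes_total,
    planted = list(spliceosome = list(size = e$planted_size,
                                      delta = e$planted_delta)),
    samples_per_group = e$samples_per_group, noise_sd = e$noise_sd)
  datasets <- lapply(sim$datasets, function(ds) {
    expression_dataset(ds$dataset_id, quantile_normalize(ds$values),
                       ds$group_of, ds$time_of)
  })
  de <- lapply(datasets, moderated_two_group_test)
  for (id in names(de))
    save_tsv(de[[id]], paste0("de_", id, ".tsv"))
  meta <- aggregate_datasets(de, r = config$meta$wilkinson_r,
                             alpha = config$meta$alpha,
                             min_datasets = config$meta$min_datasets)
  save_tsv(meta, "meta_genes.tsv")
  planted_genes <- sim$truth$gene[sim$truth$planted_set != ""]
  gene_sets <- list(spliceosome_planted = planted_genes)
  hit_down <- meta$gene[meta$significant & meta$consistent == "down"]
  enrich <- if (length(hit_down) > 0)
    hypergeometric_enrichment(hit_down, gene_sets, meta$gene)
  else data.frame(set = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p = numeric(),
                  q = numeric())
  save_tsv(enrich, "enrichment_down.tsv")

  ## splicing -> recurrence -> intron ORF
  s <- config$splicing
  splice_dir <- file.path(out_dir, "splice_tables")
  splice_sim <- gen_splice_tables(seed + 1L, splice_dir,
                                  n_samples = s$n_samples)
  events <- lapply(splice_sim$samples, function(sid) {
    filter_significant(
      read_rmats_tables(file.path(splice_dir, sid), sid,
                        sample1 = "treated"),
      fdr_max = s$fdr_max, min_abs_diff = s$min_abs_diff)
  })
  names(events) <- splice_sim$samples
  recurrent <- find_recurrent(events, min_fraction = s$min_fraction)
  save_tsv(recurrent[, c("event_type", "chrom", "strand", "coords",
                         "sign", "n_samples", "mean_inc_diff")],
           "recurrent_events.tsv")
  ts_sum <- type_summary(recurrent)
  save_tsv(data.frame(event_type = names(ts_sum$type_counts),
                      count = ts_sum$type_counts,
                      row.names = NULL), "event_type_counts.tsv")
  tx <- gen_transcripts(seed + 2L)
  scan <- batch_scan(tx$models)
  save_tsv(scan$results, "intron_stop_scan.tsv")

  ## time-course clustering
  tcf <- config$timecluster
  tc <- gen_timecourse(seed + 3L)
  fit <- fuzzy_cmeans(tc$data, c = tcf$c, m = tcf$m, seed = seed + 3L)
  trends <- vapply(seq_len(tcf$c), function(j)
    cluster_trend(fit, j)$label, character(1))
  assign <- cluster_gene_assignment(fit, tcf$min_membership)
  save_tsv(data.frame(gene = names(assign), cluster = assign,
                      round(fit$membership, 6), check.names = FALSE),
           "timecluster_membership.tsv")
  save_tsv(data.frame(cluster = seq_len(tcf$c), trend = trends,
                      round(fit$centers, 6), check.names = FALSE),
           "timecluster_centers.tsv")

  ## TF co-regulation network
  nw <- config$network
  tf_fix <- gen_tf_fixture(seed + 4L, n_datasets = nw$n_datasets,
                           window = nw$window)
  pairs <- lapply(tf_fix$datasets, function(ds)
    correlated_pairs(ds, tf_fix$splicing_genes, tf_fix$mitotic_genes,
                     rho_min = nw$rho_min, alpha = nw$alpha))
  tf_map <- build_tf_map(tf_fix$peaks, tf_fix$tss, window = nw$window)
  net <- common_tfs(pairs, tf_map)
  save_tsv(net$edges, "network_edges.tsv")
  save_tsv(data.frame(tf = net$common_tfs), "common_tfs.tsv")

  ## set overlaps on the meta result
  down_set <- hit_down
  venn <- venn_counts(list(planted = planted_genes,
                           detected_down = down_set),
                      annotation = planted_genes)
  save_tsv(venn, "venn_planted_vs_detected.tsv")
  fisher <- fisher_overlap(planted_genes, down_set, meta$gene,
                           alternative = "greater")
  save_tsv(data.frame(both = fisher$both, a_only = fisher$a_only,
                      b_only = fisher$b_only, neither = fisher$neither,
                      odds_ratio = fisher$odds_ratio,
                      p_value = fisher$p_value), "fisher_overlap.tsv")

  manifest <- list(
    tool = "splicemeta",
    version = as.character(utils::packageVersion("splicemeta")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    outputs = local({
      files <- sort(c(paths, list.files(splice_dir, recursive = TRUE,
                                        full.names = TRUE)))
      sums <- tools::md5sum(files)
      names(sums) <- sub("^/", "", sub(out_dir, "", files, fixed = TRUE))
      as.list(sums)
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(meta = meta, enrichment = enrich,
                 recurrent = recurrent, type_summary = ts_sum,
                 stop_scan = scan, clustering = fit, trends = trends,
                 network = net, venn = venn, fisher = fisher,
                 manifest = manifest, out_dir = out_dir))
}
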