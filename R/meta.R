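# Cross-study aggregation: Wilkinson order-statistic p-value combination,
# Benjamini-Hochberg FDR, and the exclusive-direction consistency filter.
#
# Heterogeneity across platforms is deliberately ignored: p-value
# combination requires minimal assumptions from the contributing studies,
# which is the point of using it over effect-size meta-analysis here.

#' Combine p-values with Wilkinson's order-statistic method
#'
#' Under the joint null the r-th smallest of k independent uniform
#' p-values follows Beta(r, k - r + 1); the combined p-value is that
#' Beta CDF evaluated at the observed r-th order statistic.  `r = 1` is
#' Tippett's minimum-p test (`1 - (1 - p_min)^k`); `r = k` uses the
#' maximum (`p_max^k`).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param r Which order statistic to use (1 <= r <= length(p_values)).
#' @return The combined p-value in (0, 1].
#' @export
wilkinson_combine <- function(p_values, r = 1) {
  k <- length(p_values)
  if (k < 1) stop("need at least one p-value")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  r <- as.integer(r)
  if (r < 1 || r > k) stop("'r' must satisfy 1 <= r <= ", k)
  p_r <- sort(p_values, partial = r)[r]
  stats::pbeta(p_r, r, k - r + 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j>=i} m * p_(j) / j`, capped at
#' 1 and mapped back to input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values in the input order (empty in, empty out).
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Aggregate per-dataset differential expression across studies
#'
#' Genes are matched across datasets by harmonized ID; per gene the
#' per-dataset p-values are combined with [wilkinson_combine()], BH-FDR
#' is applied to the combined values, and a gene is flagged consistent
#' only if it is exclusively up- or exclusively down-regulated in every
#' contributing study.  The significant-consistent set is
#' `q < alpha & consistent != "none"`.
#'
#' @param results_per_dataset Named list of per-dataset result data
#'   frames from [moderated_two_group_test()] / [welch_two_group_test()].
#' @param r Order statistic for [wilkinson_combine()] (default 1,
#'   Tippett's minimum-p).
#' @param alpha FDR threshold for the significant-consistent set
#'   (default 0.05).
#' @param min_datasets Minimum number of datasets a gene must appear in
#'   (default: all of them, matching an "in all the studies" consistency
#'   requirement).
#' @param per_dataset_alpha Optional per-dataset p-value cutoff applied
#'   before combination (default `NULL`, off).
#' @return Data frame with one row per aggregated gene: `gene`, `k`,
#'   `p_combined`, `q_value`, `consistent` (`up`/`down`/`none`),
#'   `directions` (comma-separated per-dataset directions in list order),
#'   `significant` (logical).
#' @export
aggregate_datasets <- function(results_per_dataset, r = 1, alpha = 0.05,
                               min_datasets = NULL,
                               per_dataset_alpha = NULL) {
  n_ds <- length(results_per_dataset)
  if (n_ds < 1) stop("need at least one dataset")
  if (is.null(names(results_per_dataset)))
    names(results_per_dataset) <- paste0("dataset", seq_len(n_ds))
  if (is.null(min_datasets)) min_datasets <- n_ds
  if (r > min_datasets)
    stop("'r' (", r, ") exceeds the minimum dataset count (",
         min_datasets, ")")

  long <- do.call(rbind, lapply(names(results_per_dataset), function(id) {
    de <- results_per_dataset[[id]]
    data.frame(dataset = id, gene = de$gene, p = de$p_value,
               direction = de$direction, stringsAsFactors = FALSE)
  }))
  counts <- table(long$gene)
  keep_genes <- names(counts)[counts >= min_datasets]
  if (length(keep_genes) == 0)
    stop("no gene is shared by at least ", min_datasets, " dataset(s)")
  long <- long[long$gene %in% keep_genes, ]
  split_idx <- split(seq_len(nrow(long)), long$gene)

  rows <- lapply(split_idx, function(ix) {
    p <- long$p[ix]
    dirs <- long$direction[ix]
    consistent <- if (all(dirs == "up")) "up"
      else if (all(dirs == "down")) "down" else "none"
    ok <- is.null(per_dataset_alpha) || all(p < per_dataset_alpha)
    data.frame(gene = long$gene[ix][1], k = length(ix),
               p_combined = wilkinson_combine(p, r = r),
               consistent = consistent,
               directions = paste(dirs, collapse = ","),
               passes_per_dataset = ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- bh_fdr(out$p_combined)
  out$significant <- out$q_value < alpha &
    out$consistent %in% c("up", "down") & out$passes_per_dataset
  out$passes_per_dataset <- NULL
  out[, c("gene", "k", "p_combined", "q_value", "consistent",
          "directions", "significant")]
}

#' Write aggregated meta-analysis records
#'
#' @param meta Data frame from [aggregate_datasets()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_meta_results <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
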