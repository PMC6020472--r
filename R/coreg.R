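# TF co-regulation network: Spearman co-expression between splicing- and
# mitosis-related genes, promoter binding from interval data, and the
# intersection of qualifying transcription factors across datasets.

#' Spearman correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of average-ranked values (ties receive
#' the mean rank); the two-sided p-value uses
#' `t = rho * sqrt((n-2)/(1-rho^2))` with `n - 2` degrees of freedom,
#' which is adequate at the sample sizes involved.  `rho = +/-1` yields
#' `p = 0`.  For very small samples an exact permutation p-value is
#' available.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param exact If `TRUE` (allowed only for n <= 8), the p-value is the
#'   exact two-sided permutation tail `P(|rho_perm| >= |rho_obs|)`.
#' @return List with `rho` and `p_value`.
#' @export
spearman_rho <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length")
  if (n < 4) stop("need at least 4 paired observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("Spearman correlation undefined for a constant vector")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8) stop("exact permutation p-value limited to n <= 8")
    perms <- .permutations(n)
    rho_perm <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Cross-set co-expressed gene pairs within one dataset
#'
#' Tests every (splicing gene, mitotic gene) pair by Spearman correlation
#' across the dataset's samples, applies BH-FDR over the whole tested
#' pair family within the dataset, and keeps pairs with
#' `rho > rho_min` and `q < alpha` (rho threshold strict: 0.7 exactly is
#' dropped).
#'
#' @param dataset An [expression_dataset()].
#' @param splicing_genes,mitotic_genes Character vectors of gene IDs;
#'   both are intersected with the dataset's genes first (an empty
#'   intersection is an error).  Genes present in both sets are never
#'   paired with themselves.
#' @param rho_min Correlation threshold (default 0.7).
#' @param alpha FDR threshold (default 0.05).
#' @return Data frame of retained pairs: `gene_a` (splicing set),
#'   `gene_b` (mitotic set), `rho`, `p_value`, `q_value`.
#' @export
correlated_pairs <- function(dataset, splicing_genes, mitotic_genes,
                             rho_min = 0.7, alpha = 0.05) {
  sg <- intersect(splicing_genes, dataset$genes)
  mg <- intersect(mitotic_genes, dataset$genes)
  if (length(sg) == 0)
    stop("no splicing-set gene present in dataset ", dataset$dataset_id)
  if (length(mg) == 0)
    stop("no mitotic-set gene present in dataset ", dataset$dataset_id)
  ranks <- t(apply(dataset$values[unique(c(sg, mg)), , drop = FALSE], 1,
                   rank, ties.method = "average"))
  pairs <- expand.grid(gene_a = sg, gene_b = mg,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
  n <- length(dataset$samples)
  stats_list <- mapply(function(a, b) {
    rho <- stats::cor(ranks[a, ], ranks[b, ])
    if (!is.finite(rho))
      stop("Spearman correlation undefined (constant gene: ", a, " or ",
           b, ")")
    p <- if (abs(rho) >= 1 - 1e-15) 0 else {
      t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(t_stat), df = n - 2)
    }
    c(rho, p)
  }, pairs$gene_a, pairs$gene_b)
  pairs$rho <- stats_list[1, ]
  pairs$p_value <- stats_list[2, ]
  pairs$q_value <- bh_fdr(pairs$p_value)
  out <- pairs[pairs$rho > rho_min & pairs$q_value < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read BED3+ peak intervals with a TF name column
#'
#' @param path BED file: `chrom  start  end  tf_name` (0-based,
#'   half-open, no header).
#' @return Data frame `chrom`, `start`, `end`, `tf`.
#' @export
read_bed_peaks <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("BED file needs 4+ columns (chrom start end tf)")
  names(bed)[1:4] <- c("chrom", "start", "end", "tf")
  bed[, 1:4]
}

#' Read a gene TSS table
#'
#' @param path TSV `gene  chrom  strand  tss` (0-based TSS position; one
#'   canonical TSS per gene).
#' @return Data frame with those columns.
#' @export
read_tss_table <- function(path) {
  tss <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "strand", "tss")
  if (!all(need %in% names(tss)))
    stop("TSS table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tss$gene)) stop("TSS table: one TSS per gene required")
  tss
}

#' Build a TF -> bound-genes map from peaks and TSS positions
#'
#' A TF binds a gene iff any of its peaks overlaps the strand-agnostic
#' promoter window `[tss - window, tss + window)` by at least one base.
#' Intervals are 0-based half-open, as in BED.
#'
#' @param peaks Data frame `chrom`, `start`, `end`, `tf` (see
#'   [read_bed_peaks()]).
#' @param tss Data frame `gene`, `chrom`, `strand`, `tss` (see
#'   [read_tss_table()]).
#' @param window Promoter half-width in bp (default 2000).
#' @return Object of class `TFBindingMap`: list with `targets` (named
#'   list TF -> character vector of bound genes; TFs binding nothing are
#'   absent) and `window`.
#' @export
build_tf_map <- function(peaks, tss, window = 2000) {
  if (any(peaks$end <= peaks$start))
    stop("peak interval with end <= start")
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$start + 1L,
                                  end = peaks$end))
  prom_gr <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(start = pmax(tss$tss - window, 0) + 1L,
                                end = tss$tss + window))
  hits <- GenomicRanges::findOverlaps(peak_gr, prom_gr, minoverlap = 1L,
                                      ignore.strand = TRUE)
  tf_of_hit <- peaks$tf[S4Vectors::queryHits(hits)]
  gene_of_hit <- tss$gene[S4Vectors::subjectHits(hits)]
  targets <- lapply(split(gene_of_hit, tf_of_hit),
                    function(g) sort(unique(g)))
  structure(list(targets = targets, window = window),
            class = "TFBindingMap")
}

#' Transcription factors common to every dataset's co-expressed pairs
#'
#' Per dataset, a TF qualifies if it binds the promoters of both members
#' of at least one retained co-expressed pair; the result is the
#' intersection of the qualifying TF sets over all datasets, plus the
#' annotated graph edges.
#'
#' @param pairs_per_dataset Named list (dataset id -> data frame from
#'   [correlated_pairs()]).
#' @param tf_map A [build_tf_map()] result.
#' @return List with `common_tfs` (character, possibly empty),
#'   `per_dataset` (named list of per-dataset TF sets), and `edges`
#'   (data frame `tf`, `gene_a`, `gene_b`, `dataset`, `rho`, restricted
#'   to common TFs).
#' @export
common_tfs <- function(pairs_per_dataset, tf_map) {
  if (length(pairs_per_dataset) == 0 ||
      all(vapply(pairs_per_dataset, nrow, integer(1)) == 0))
    stop("need at least one dataset with at least one retained pair")
  per_dataset <- lapply(pairs_per_dataset, function(pairs) {
    qual <- vapply(names(tf_map$targets), function(tf) {
      bound <- tf_map$targets[[tf]]
      any(pairs$gene_a %in% bound & pairs$gene_b %in% bound)
    }, logical(1))
    names(tf_map$targets)[qual]
  })
  common <- Reduce(intersect, per_dataset)
  edges <- do.call(rbind, lapply(names(pairs_per_dataset), function(id) {
    pairs <- pairs_per_dataset[[id]]
    do.call(rbind, lapply(common, function(tf) {
      bound <- tf_map$targets[[tf]]
      sel <- pairs$gene_a %in% bound & pairs$gene_b %in% bound
      if (!any(sel)) return(NULL)
      data.frame(tf = tf, gene_a = pairs$gene_a[sel],
                 gene_b = pairs$gene_b[sel], dataset = id,
                 rho = pairs$rho[sel], stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(edges))
    edges <- data.frame(tf = character(), gene_a = character(),
                        gene_b = character(), dataset = character(),
                        rho = numeric(), stringsAsFactors = FALSE)
  if (length(common) == 0)
    message("no transcription factor qualifies in every dataset")
  list(common_tfs = sort(common), per_dataset = per_dataset,
       edges = edges)
}
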