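# Expression matrix input, normalization and transforms.
#
# The pipeline starts from numeric gene-by-sample matrices: vendor binary
# array formats (CEL/IDAT) and their background-correction machinery are
# deliberately out of scope.  Matrices are carried in a lightweight
# "ExpressionDataset" S3 object together with sample group labels
# (control/treated) and optional time annotations.

#' Construct an ExpressionDataset
#'
#' Bundles a gene-by-sample expression matrix with its sample group labels
#' (`control` / `treated`) and optional treatment times.  All downstream
#' statistics assume the matrix is on the log2 scale after normalization;
#' use [log2_transform()] and [quantile_normalize()] to get there from
#' linear-scale input.
#'
#' @param dataset_id Short text label for the study.
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene IDs) and colnames (sample IDs).
#' @param group_of Named character vector mapping every sample ID to
#'   `"control"` or `"treated"`.
#' @param time_of Optional named numeric vector mapping sample IDs to
#'   treatment time in hours (non-negative).
#' @param log2_scale Logical flag declaring whether `values` is already on
#'   the log2 scale.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `dataset_id`, `genes`, `samples`, `values`, `group_of`, `time_of`,
#'   `log2_scale`.
#' @export
expression_dataset <- function(dataset_id, values, group_of, time_of = NULL,
                               log2_scale = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene/probe IDs: ",
         paste(utils::head(unique(rownames(values)[duplicated(rownames(values))]), 5),
               collapse = ", "))
  if (!all(is.finite(values)))
    stop("'values' contains non-finite entries")
  samples <- colnames(values)
  missing <- setdiff(samples, names(group_of))
  if (length(missing))
    stop("no group label for sample(s): ", paste(missing, collapse = ", "))
  group_of <- group_of[samples]
  if (!all(group_of %in% c("control", "treated")))
    stop("group labels must be 'control' or 'treated'")
  if (!is.null(time_of)) {
    time_of <- time_of[samples]
    if (any(is.na(time_of)) || any(time_of < 0))
      stop("'time_of' must give a non-negative time for every sample")
  }
  structure(
    list(dataset_id = as.character(dataset_id)[1],
         genes = rownames(values), samples = samples, values = values,
         group_of = group_of, time_of = time_of,
         log2_scale = isTRUE(log2_scale)),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s': %d genes x %d samples (%d control, %d treated)%s\n",
              x$dataset_id, length(x$genes), length(x$samples),
              sum(x$group_of == "control"), sum(x$group_of == "treated"),
              if (x$log2_scale) ", log2 scale" else ", linear scale"))
  invisible(x)
}

#' Read an expression table and its sample group assignment
#'
#' The expression file is tab-separated with a header row
#' `gene_id<TAB>sample1<TAB>...` and one row per probe or gene; every cell
#' must be numeric (missing values are rejected rather than imputed).  The
#' group specification maps each sample to `control` or `treated`, with an
#' optional `time_h` column for time-course designs.
#'
#' @param path Path to the tab-separated expression file.
#' @param group_spec Either a path to a two/three-column TSV
#'   (`sample<TAB>group[<TAB>time_h]`) or a data.frame with those columns.
#' @param dataset_id Label for the dataset; defaults to the file name.
#' @param log2_scale Declares the scale of the stored values (see
#'   [expression_dataset()]).
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, group_spec, dataset_id = NULL,
                            log2_scale = TRUE) {
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", sep = "\t")
  if (ncol(tab) < 2) stop("expression file needs a gene column plus samples")
  gene_ids <- tab[[1]]
  raw <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                 dimnames = dimnames(raw)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at row %d (gene '%s'), column '%s'",
                 bad[1, 1], gene_ids[bad[1, 1]], colnames(raw)[bad[1, 2]]))
  }
  rownames(num) <- gene_ids
  if (is.character(group_spec) && length(group_spec) == 1) {
    group_spec <- utils::read.delim(group_spec, header = TRUE,
                                    check.names = FALSE, sep = "\t")
  }
  if (!all(c("sample", "group") %in% names(group_spec)))
    stop("group_spec needs 'sample' and 'group' columns")
  group_of <- stats::setNames(as.character(group_spec$group),
                              as.character(group_spec$sample))
  time_of <- NULL
  if ("time_h" %in% names(group_spec))
    time_of <- stats::setNames(as.numeric(group_spec$time_h),
                               as.character(group_spec$sample))
  expression_dataset(dataset_id, num, group_of, time_of = time_of,
                     log2_scale = log2_scale)
}

#' Write an expression dataset (round-trips through [read_expression()])
#'
#' @param dataset An [expression_dataset()].
#' @param path Output path for the expression TSV.
#' @param group_path Optional output path for the sample/group TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(dataset, path, group_path = NULL) {
  df <- data.frame(gene_id = dataset$genes, dataset$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(group_path)) {
    g <- data.frame(sample = dataset$samples,
                    group = unname(dataset$group_of))
    if (!is.null(dataset$time_of)) g$time_h <- unname(dataset$time_of)
    utils::write.table(g, group_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Quantile-normalize the columns of a matrix
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' across-column mean of sorted values.  Ties within a column receive the
#' mean of the reference values across their tied rank span, the de-facto
#' standard algorithm for expression arrays.
#'
#' @param values Numeric matrix (genes x samples) with finite entries.
#' @return Matrix of the same shape; column means are equal and
#'   within-column rank order is preserved.  A single-column input is
#'   returned unchanged with a warning.
#' @export
quantile_normalize <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (!all(is.finite(values))) stop("'values' contains non-finite entries")
  if (ncol(values) < 2) {
    warning("single-column input: quantile normalization is a no-op")
    return(values)
  }
  ref <- rowMeans(apply(values, 2, sort))
  out <- values
  for (j in seq_len(ncol(values))) {
    col <- values[, j]
    v <- numeric(length(col))
    v[order(col)] <- ref
    # tied entries share the mean reference value over their rank span
    out[, j] <- stats::ave(v, match(col, col), FUN = mean)
  }
  out
}

#' Elementwise log2 transform with offset
#'
#' @param values Numeric matrix or vector.
#' @param offset Non-negative constant added before taking logs.
#' @return `log2(values + offset)`; errors if any entry is non-positive
#'   after the offset.
#' @export
log2_transform <- function(values, offset = 0) {
  if (offset < 0) stop("'offset' must be non-negative")
  if (any(values + offset <= 0))
    stop("log2_transform: value + offset <= 0 encountered")
  log2(values + offset)
}

#' Drop rows undetected in every sample
#'
#' Optional pre-filter mirroring bead-array detection calls: a row is kept
#' unless its detection p-value exceeds the threshold in all samples.
#'
#' @param dataset An [expression_dataset()].
#' @param detection_p Matrix of detection p-values, same shape and dimnames
#'   as `dataset$values`.
#' @param threshold Detection p-value cutoff (default 0.05).
#' @return The filtered dataset.
#' @export
detection_filter <- function(dataset, detection_p, threshold = 0.05) {
  stopifnot(identical(dim(detection_p), dim(dataset$values)))
  keep <- rowSums(detection_p <= threshold) > 0
  expression_dataset(dataset$dataset_id,
                     dataset$values[keep, , drop = FALSE],
                     dataset$group_of, dataset$time_of, dataset$log2_scale)
}

#' Read a probe-to-gene identifier map
#'
#' Two-column TSV `probe<TAB>refseq`; many probes may map to one gene, but
#' empty target IDs are rejected.
#'
#' @param path Path to the map file.
#' @return Data frame with columns `probe`, `refseq`.
#' @export
read_gene_id_map <- function(path) {
  m <- utils::read.delim(path, header = TRUE, check.names = FALSE, sep = "\t",
                         colClasses = "character")
  names(m)[1:2] <- c("probe", "refseq")
  if (any(!nzchar(m$refseq) | is.na(m$refseq)))
    stop("gene ID map contains empty target IDs")
  m
}

#' Collapse probe-level rows to one row per gene
#'
#' Harmonizes platforms onto shared (RefSeq-style) gene identifiers so
#' datasets can be matched in the meta-analysis.  Probes absent from the
#' map are dropped (a count is reported via `message`).
#'
#' @param dataset An [expression_dataset()] with probe-level rows.
#' @param idmap Data frame with columns `probe`, `refseq` (see
#'   [read_gene_id_map()]).
#' @param method `"max-mean-probe"` keeps, per gene, the probe with the
#'   highest mean signal (the common microarray convention); `"mean"`
#'   averages all probes of a gene elementwise.
#' @return An [expression_dataset()] with one row per gene ID.
#' @export
collapse_probes <- function(dataset, idmap,
                            method = c("max-mean-probe", "mean")) {
  method <- match.arg(method)
  if (any(!nzchar(idmap$refseq) | is.na(idmap$refseq)))
    stop("gene ID map contains empty target IDs")
  map <- stats::setNames(as.character(idmap$refseq), as.character(idmap$probe))
  target <- map[dataset$genes]
  dropped <- sum(is.na(target))
  if (dropped > 0)
    message(dropped, " unmapped probe(s) dropped")
  keep <- !is.na(target)
  if (!any(keep)) stop("no probes left after identifier mapping")
  vals <- dataset$values[keep, , drop = FALSE]
  gene <- target[keep]
  if (method == "mean") {
    collapsed <- rowsum(vals, group = gene, reorder = TRUE) /
      as.vector(table(gene)[sort(unique(gene))])
  } else {
    means <- rowMeans(vals)
    ord <- order(gene, -means)
    first <- !duplicated(gene[ord])
    sel <- ord[first]
    collapsed <- vals[sel, , drop = FALSE]
    rownames(collapsed) <- gene[sel]
    collapsed <- collapsed[sort(rownames(collapsed)), , drop = FALSE]
  }
  expression_dataset(dataset$dataset_id, as.matrix(collapsed),
                     dataset$group_of, dataset$time_of, dataset$log2_scale)
}

#' Z-score each row of a matrix
#'
#' Centers and scales every gene to mean 0, sample (n-1) standard
#' deviation 1.  Constant rows become rows of zeros (with a warning)
#' rather than NaN so downstream clustering never sees non-finite values.
#'
#' @param values Numeric matrix (genes x samples).
#' @return Matrix of z-scores, same shape and dimnames.
#' @export
zscore_rows <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  m <- rowMeans(values)
  s <- apply(values, 1, stats::sd)
  const <- s == 0 | !is.finite(s)
  if (any(const)) {
    warning(sum(const), " constant row(s) mapped to zeros")
    s[const] <- 1
  }
  out <- (values - m) / s
  out[const, ] <- 0
  out
}
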