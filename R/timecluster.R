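# Soft clustering of z-scored expression time courses with fuzzy
# c-means, plus hard assignment and per-cluster trend labeling.
#
# Fuzzy c-means minimizes sum_ic u_ic^m ||x_i - v_c||^2 subject to each
# gene's memberships summing to 1; the fuzzifier m > 1 controls how soft
# the partition is.  Initialization samples c distinct data rows as
# starting centers (seeded), which is reproducible and converges faster
# than random points.

#' Build a time-series matrix from an expression dataset
#'
#' Averages replicate samples within each timepoint, orders columns by
#' time, and z-scores rows.  Downstream trend interpretation assumes at
#' least four timepoints.
#'
#' @param dataset An [expression_dataset()] whose `time_of` is set.
#' @param min_timepoints Minimum number of distinct timepoints
#'   (default 4).
#' @return List of class `TimeSeriesMatrix`: `genes`, `timepoints`
#'   (hours, increasing), `values` (gene x timepoint, row z-scored).
#' @export
timeseries_matrix <- function(dataset, min_timepoints = 4) {
  if (is.null(dataset$time_of))
    stop("dataset has no time annotation")
  tp <- sort(unique(dataset$time_of))
  if (length(tp) < min_timepoints)
    stop("need at least ", min_timepoints, " distinct timepoints, got ",
         length(tp))
  vals <- vapply(tp, function(t) {
    cols <- dataset$samples[dataset$time_of == t]
    rowMeans(dataset$values[, cols, drop = FALSE])
  }, numeric(length(dataset$genes)))
  vals <- matrix(vals, nrow = length(dataset$genes),
                 dimnames = list(dataset$genes, paste0("t", tp)))
  structure(list(genes = dataset$genes, timepoints = tp,
                 values = zscore_rows(vals)),
            class = "TimeSeriesMatrix")
}

.sq_dist_to_centers <- function(x, centers) {
  # genes x c matrix of squared Euclidean distances
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  pmax(d2, 0)
}

.fcm_memberships <- function(d2, m) {
  u <- matrix(0, nrow(d2), ncol(d2))
  zero <- d2 < .Machine$double.eps
  sing <- rowSums(zero) > 0
  if (any(sing)) {       # coincident with a center: all mass there
    for (i in which(sing)) u[i, which(zero[i, ])[1]] <- 1
  }
  reg <- which(!sing)
  if (length(reg)) {
    w <- d2[reg, , drop = FALSE]^(-1 / (m - 1))
    u[reg, ] <- w / rowSums(w)
  }
  u
}

#' Fuzzy c-means clustering
#'
#' Alternating optimization: memberships
#' `u_ic = 1 / sum_j (d_ic/d_jc)^(2/(m-1))`, centers
#' `v_c = sum_i u_ic^m x_i / sum_i u_ic^m`, stopping when the objective
#' `sum u^m d^2` changes by less than `tol`.  A point coincident with a
#' center receives membership 1 for that center (the standard
#' singularity rule).
#'
#' @param data A `TimeSeriesMatrix` (see [timeseries_matrix()]) or a
#'   plain numeric matrix of profiles.
#' @param c Number of clusters (2 <= c < number of rows).
#' @param m Fuzzifier, > 1 (default 2).
#' @param seed Integer seed for the data-row initialization.
#' @param tol Convergence tolerance on the objective (default 1e-6).
#' @param max_iter Iteration cap (default 500).
#' @return Object of class `FuzzyClustering`: `c`, `m`, `centers`
#'   (c x timepoints), `membership` (genes x c, rows sum to 1),
#'   `objective`, `objective_trace`, `n_iter`.
#' @export
fuzzy_cmeans <- function(data, c, m = 2, seed = 1, tol = 1e-6,
                         max_iter = 500) {
  x <- if (inherits(data, "TimeSeriesMatrix")) data$values else data
  if (!is.matrix(x)) stop("'data' must be a matrix or TimeSeriesMatrix")
  n <- nrow(x)
  if (c < 2) stop("'c' must be at least 2")
  if (c >= n) stop("'c' must be smaller than the number of genes (", n, ")")
  if (m <= 1) stop("fuzzifier 'm' must be > 1")
  uniq <- x[!duplicated(round(x, 12)), , drop = FALSE]
  if (nrow(uniq) < c)
    stop("fewer than ", c, " distinct profiles available for initialization")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  centers <- uniq[sample(nrow(uniq), c), , drop = FALSE]
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  obj_trace <- numeric(0)
  u <- NULL
  for (iter in seq_len(max_iter)) {
    d2 <- .sq_dist_to_centers(x, centers)
    u <- .fcm_memberships(d2, m)
    obj <- sum(u^m * d2)
    obj_trace <- c(obj_trace, obj)
    if (iter > 1 && abs(obj_trace[iter - 1] - obj) < tol) break
    um <- u^m
    denom <- colSums(um)
    centers <- (t(um) %*% x) / denom
  }
  rownames(centers) <- paste0("cluster", seq_len(c))
  dimnames(u) <- list(rownames(x), rownames(centers))
  structure(list(c = c, m = m, centers = centers, membership = u,
                 objective = obj_trace[length(obj_trace)],
                 objective_trace = obj_trace, n_iter = length(obj_trace)),
            class = "FuzzyClustering")
}

#' Hard cluster assignment from a fuzzy clustering
#'
#' @param clustering A [fuzzy_cmeans()] result.
#' @param min_membership Assign a gene to its argmax cluster only if the
#'   maximum membership reaches this threshold (default 0.5); otherwise
#'   the gene is unassigned (`NA`).
#' @return Named integer vector (gene -> cluster index, `NA` for
#'   unassigned).
#' @export
cluster_gene_assignment <- function(clustering, min_membership = 0.5) {
  if (min_membership < 0 || min_membership > 1)
    stop("'min_membership' must lie in [0, 1]")
  u <- clustering$membership
  best <- max.col(u, ties.method = "first")
  top <- u[cbind(seq_len(nrow(u)), best)]
  out <- ifelse(top >= min_membership, best, NA_integer_)
  stats::setNames(as.integer(out), rownames(u))
}

#' Per-cluster mean trajectory and monotonicity label
#'
#' The trajectory is the membership^m-weighted mean of all profiles
#' (which is exactly the converged cluster center); the monotonicity
#' label is judged on the center: strictly decreasing across all
#' timepoints gives `"decreasing"`, strictly increasing
#' `"increasing"`, anything else `"non-monotone"`.
#'
#' @param clustering A [fuzzy_cmeans()] result.
#' @param cluster Cluster index in `1..c`.
#' @param data Optional matrix/`TimeSeriesMatrix` used for the weighted
#'   trajectory; defaults to reporting the stored center.
#' @return List with `trajectory` (per-timepoint means) and `label`.
#' @export
cluster_trend <- function(clustering, cluster, data = NULL) {
  if (cluster < 1 || cluster > clustering$c)
    stop("invalid cluster index: ", cluster)
  if (is.null(data)) {
    traj <- clustering$centers[cluster, ]
  } else {
    x <- if (inherits(data, "TimeSeriesMatrix")) data$values else data
    w <- clustering$membership[, cluster]^clustering$m
    traj <- colSums(w * x) / sum(w)
  }
  ctr <- clustering$centers[cluster, ]
  dd <- diff(ctr)
  label <- if (length(dd) && all(dd < 0)) "decreasing"
    else if (length(dd) && all(dd > 0)) "increasing"
    else "non-monotone"
  list(trajectory = traj, label = label)
}

#' Sweep the cluster count and report minimum centroid distances
#'
#' For each candidate `c` the clustering is run and the minimum pairwise
#' distance between converged centers recorded; as `c` grows past the
#' true structure, centers crowd together and the minimum distance
#' collapses.  The suggested `c` is the elbow: the candidate after which
#' the largest relative drop occurs.
#'
#' @param data Matrix or `TimeSeriesMatrix`.
#' @param c_range Candidate cluster counts (default 4:12).
#' @param m,seed,tol,max_iter Passed to [fuzzy_cmeans()].
#' @return List with `table` (data frame `c`, `min_center_distance`) and
#'   `suggested_c`.
#' @export
select_cluster_number <- function(data, c_range = 4:12, m = 2, seed = 1,
                                  tol = 1e-6, max_iter = 500) {
  x <- if (inherits(data, "TimeSeriesMatrix")) data$values else data
  c_range <- c_range[c_range < nrow(x)]
  dmin <- vapply(c_range, function(cc) {
    fit <- fuzzy_cmeans(x, c = cc, m = m, seed = seed, tol = tol,
                        max_iter = max_iter)
    min(stats::dist(fit$centers))
  }, numeric(1))
  drop_ratio <- dmin[-length(dmin)] / pmax(dmin[-1], .Machine$double.eps)
  suggested <- if (length(drop_ratio)) c_range[which.max(drop_ratio)]
    else c_range[1]
  list(table = data.frame(c = c_range, min_center_distance = dmin),
       suggested_c = suggested)
}

#' Write fuzzy clustering outputs
#'
#' @param clustering A [fuzzy_cmeans()] result.
#' @param membership_path TSV of gene, hard cluster, memberships.
#' @param centers_path CSV of cluster centers.
#' @param min_membership Threshold for the hard assignment column.
#' @return Invisibly, the membership path.
#' @export
write_clustering <- function(clustering, membership_path, centers_path,
                             min_membership = 0.5) {
  assign <- cluster_gene_assignment(clustering, min_membership)
  df <- data.frame(gene = rownames(clustering$membership),
                   cluster = assign, clustering$membership,
                   check.names = FALSE)
  utils::write.table(df, membership_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(data.frame(cluster = rownames(clustering$centers),
                              clustering$centers, check.names = FALSE),
                   centers_path, row.names = FALSE, quote = FALSE)
  invisible(membership_path)
}
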