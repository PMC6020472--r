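# Gene-set over-representation, Fisher exact overlap, and Venn region
# summaries.
#
# The universe (background) is explicit and mandatory everywhere:
# defaulting to "all genes" silently inflates significance, so the
# caller must state what was actually measured or detected.

#' Read a GMT gene-set collection
#'
#' Standard tab-separated format: `name<TAB>description<TAB>gene1...`,
#' one set per line.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (the descriptions are
#'   dropped); empty sets and duplicate names are rejected.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) {
    if (length(f) < 3) stop("GMT line with no genes: ", f[1])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names in GMT")
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of a query set
#'
#' For each collection set S, tests whether the query hits S more often
#' than random draws from the universe would:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`, where
#' `N = |universe|`, `K = |S n universe|`, `n = |query|`,
#' `k = |query n S|`.  BH-FDR is applied over the collection.
#'
#' @param query Character vector of gene IDs, a subset of `universe`.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]); each is
#'   intersected with the universe before testing.
#' @param universe Character vector: the measured background.
#' @return Data frame sorted by `q`: `set`, `k`, `K`, `n`, `N`, `p`,
#'   `q`.
#' @export
hypergeometric_enrichment <- function(query, sets, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0) stop("empty universe")
  if (length(query) == 0) stop("empty query set")
  extra <- setdiff(query, universe)
  if (length(extra))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    K <- length(s)
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$q, out$p, out$set), ]
  rownames(out) <- NULL
  out
}

#' Fisher's exact test on the overlap of two gene sets
#'
#' Builds the 2x2 table (both, A only, B only, neither) over an explicit
#' universe.  `alternative = "greater"` is the hypergeometric upper tail
#' at the observed overlap; `"two.sided"` sums the probabilities of all
#' tables no more probable than the observed one (the dominant
#' convention).  The odds ratio is the sample odds ratio
#' `(both * neither) / (a_only * b_only)`, infinite when the denominator
#' is zero.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of the background.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return List of class `OverlapTest`: `both`, `a_only`, `b_only`,
#'   `neither`, `odds_ratio`, `p_value`, `alternative`.
#' @export
fisher_overlap <- function(set_a, set_b, universe,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  off <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(off))
    stop("set member(s) outside the universe: ",
         paste(utils::head(unique(off), 5), collapse = ", "))
  N <- length(universe)
  both <- length(intersect(set_a, set_b))
  a_only <- length(set_a) - both
  b_only <- length(set_b) - both
  neither <- N - both - a_only - b_only
  nA <- length(set_a); nB <- length(set_b)
  support <- max(0, nA + nB - N):min(nA, nB)
  dens <- stats::dhyper(support, nA, N - nA, nB)
  if (alternative == "greater") {
    p <- sum(dens[support >= both])
  } else {
    d_obs <- stats::dhyper(both, nA, N - nA, nB)
    p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  }
  or <- if (a_only * b_only == 0) {
    if (both * neither == 0) NaN else Inf
  } else (both * neither) / (a_only * b_only)
  structure(list(both = both, a_only = a_only, b_only = b_only,
                 neither = neither, odds_ratio = or,
                 p_value = min(p, 1), alternative = alternative),
            class = "OverlapTest")
}

#' @export
print.OverlapTest <- function(x, ...) {
  cat(sprintf(paste0("Fisher overlap test (%s): both=%d, A only=%d, ",
                     "B only=%d, neither=%d\n  odds ratio=%g, p=%g\n"),
              x$alternative, x$both, x$a_only, x$b_only, x$neither,
              x$odds_ratio, x$p_value))
  invisible(x)
}

#' Venn region counts with annotation sub-counts
#'
#' Counts the disjoint regions of 2 or 3 named sets, and within each
#' region the members that also belong to an annotation set (e.g.
#' spliceosomal genes), mirroring the "count/annotated" display of
#' multi-set summaries.
#'
#' @param named_sets Named list of 2 or 3 character vectors.
#' @param annotation Character vector (may be empty).
#' @return Data frame: `region` (e.g. `"A&B"`, set-name based), `count`,
#'   `annotated`.  Region counts partition the union.
#' @export
venn_counts <- function(named_sets, annotation = character(0)) {
  k <- length(named_sets)
  if (k < 2 || k > 3) stop("venn_counts supports 2 or 3 sets")
  if (is.null(names(named_sets)))
    names(named_sets) <- LETTERS[seq_len(k)]
  all_genes <- unique(unlist(named_sets))
  member <- vapply(named_sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  member <- matrix(member, ncol = k)
  pattern <- apply(member, 1, function(b) {
    paste(names(named_sets)[b], collapse = "&")
  })
  regions <- unlist(lapply(seq_len(k), function(i) {
    apply(utils::combn(names(named_sets), i), 2, paste, collapse = "&")
  }))
  counts <- table(factor(pattern, levels = regions))
  annotated <- vapply(regions, function(r) {
    sum(pattern == r & all_genes %in% annotation)
  }, numeric(1))
  data.frame(region = regions, count = as.integer(counts),
             annotated = as.integer(annotated), row.names = NULL,
             stringsAsFactors = FALSE)
}
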