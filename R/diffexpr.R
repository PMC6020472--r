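# Per-dataset two-group differential expression.
#
# The meta-analysis only consumes per-gene (p-value, direction) pairs, so
# the test here is self-contained: an empirical-Bayes moderated t in which
# per-gene residual variances are shrunk toward a scaled
# inverse-chi-square prior fitted by moment-matching on log-variances,
# plus a Welch fallback for users who prefer an unmoderated statistic.

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration with a
#' bisection safeguard.  Used to recover the prior degrees of freedom from
#' the excess variance of log sample variances.
#'
#' @param y Positive target value.
#' @param tol Relative convergence tolerance.
#' @return The solution `x`; `Inf` when `y` is (numerically) zero or
#'   negative.
#' @keywords internal
trigamma_inverse <- function(y, tol = 1e-8) {
  if (!is.finite(y) || y <= 1e-12) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  # bracket the root: trigamma is strictly decreasing on (0, Inf)
  lo <- 1e-8; hi <- 1e8
  x <- 0.5 + 1 / y
  for (iter in seq_len(100)) {
    f <- trigamma(x) - y
    if (f > 0) lo <- max(lo, x) else hi <- min(hi, x)
    step <- f / psigamma(x, deriv = 2)   # Newton: f' = psigamma(, 2) < 0
    x_new <- x - step
    if (!is.finite(x_new) || x_new <= lo || x_new >= hi)
      x_new <- (lo + hi) / 2             # safeguard
    if (abs(x_new - x) < tol * abs(x)) return(x_new)
    x <- x_new
  }
  x
}

#' Fit a scaled inverse-chi-square prior to gene-level variances
#'
#' Moment-matches the mean and variance of `log(s2)` to their
#' digamma/trigamma expressions under the hierarchical model
#' `s2_g | sigma2_g ~ sigma2_g * chisq(df)/df`,
#' `sigma2_g ~ s02 * d0 / chisq(d0)`.
#'
#' @param s2 Vector of per-gene residual variances.
#' @param df Residual degrees of freedom shared by all genes.
#' @param d0_cap Prior df above this value are treated as infinite.
#' @return List with `d0` (prior degrees of freedom, possibly `Inf`) and
#'   `s02` (prior variance).  `d0 = 0` signals that no prior could be
#'   fitted (fewer than two positive variances).
#' @export
fit_variance_prior <- function(s2, df, d0_cap = 1e6) {
  e <- log(s2[is.finite(s2) & s2 > 0])
  if (length(e) < 2) return(list(d0 = 0, s02 = NA_real_))
  emean <- mean(e)
  evar <- stats::var(e)
  target <- evar - trigamma(df / 2)
  if (target <= 0) {
    d0 <- Inf
  } else {
    d0 <- 2 * trigamma_inverse(target)
    if (d0 > d0_cap) d0 <- Inf
  }
  if (is.infinite(d0)) {
    s02 <- exp(emean - digamma(df / 2) + log(df / 2))
  } else {
    s02 <- exp(emean - digamma(df / 2) + log(df / 2) -
                 log(d0 / 2) + digamma(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

.group_split <- function(dataset) {
  ctrl <- dataset$samples[dataset$group_of == "control"]
  trt <- dataset$samples[dataset$group_of == "treated"]
  if (length(ctrl) < 2 || length(trt) < 2)
    stop("each group needs at least 2 samples (control: ", length(ctrl),
         ", treated: ", length(trt), ")")
  list(ctrl = dataset$values[, ctrl, drop = FALSE],
       trt = dataset$values[, trt, drop = FALSE])
}

.de_result <- function(genes, log2fc, t_stat, p_value) {
  direction <- ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", "zero"))
  data.frame(gene = genes, log2fc = log2fc, t_stat = t_stat,
             p_value = p_value, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Moderated two-group differential expression test
#'
#' Per gene, the treated-minus-control difference of means is tested with
#' a t-statistic whose denominator uses the empirical-Bayes shrunken
#' variance `(d0*s02 + df*s2_g) / (d0 + df)`; the reference distribution
#' gains the prior degrees of freedom (`d0 + df`).  When the prior cannot
#' be estimated (a single gene) the statistic reduces to the ordinary
#' pooled-variance t.
#'
#' @param dataset An [expression_dataset()] on the log2 scale with at
#'   least two samples per group.
#' @return Data frame with one row per gene: `gene`, `log2fc`
#'   (treated mean minus control mean), `t_stat`, `p_value`, `direction`
#'   (`up`/`down`/`zero`).
#' @seealso [welch_two_group_test()] for the unmoderated fallback.
#' @export
moderated_two_group_test <- function(dataset) {
  g <- .group_split(dataset)
  n1 <- ncol(g$trt); n2 <- ncol(g$ctrl)
  df <- n1 + n2 - 2
  d <- rowMeans(g$trt) - rowMeans(g$ctrl)
  ss <- rowSums((g$trt - rowMeans(g$trt))^2) +
    rowSums((g$ctrl - rowMeans(g$ctrl))^2)
  s2 <- ss / df
  prior <- fit_variance_prior(s2, df)
  if (prior$d0 == 0) {            # prior estimation impossible: pooled t
    s2_tilde <- s2
    df_total <- df
  } else if (is.infinite(prior$d0)) {
    s2_tilde <- rep(prior$s02, length(s2))
    df_total <- Inf
  } else {
    s2_tilde <- (prior$d0 * prior$s02 + df * s2) / (prior$d0 + df)
    df_total <- prior$d0 + df
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t_stat <- ifelse(d == 0, 0, d / se)
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  p[d == 0] <- 1
  .de_result(dataset$genes, d, t_stat, pmin(p, 1))
}

#' Welch two-group test (unmoderated fallback)
#'
#' Ordinary per-gene Welch t with Satterthwaite degrees of freedom; same
#' record contract as [moderated_two_group_test()].
#'
#' @inheritParams moderated_two_group_test
#' @return Data frame as in [moderated_two_group_test()].
#' @export
welch_two_group_test <- function(dataset) {
  g <- .group_split(dataset)
  n1 <- ncol(g$trt); n2 <- ncol(g$ctrl)
  d <- rowMeans(g$trt) - rowMeans(g$ctrl)
  v1 <- apply(g$trt, 1, stats::var)
  v2 <- apply(g$ctrl, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  t_stat <- ifelse(d == 0, 0, d / sqrt(se2))
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  p[d == 0] <- 1
  p[se2 == 0 & d != 0] <- 0
  t_stat[se2 == 0 & d != 0] <- sign(d[se2 == 0 & d != 0]) * Inf
  .de_result(dataset$genes, d, t_stat, pmin(p, 1))
}

#' Twofold-change style abundance filter
#'
#' Splits proteins (or any analytes) into increased/decreased sets by a
#' fold-change threshold on strictly positive abundances.  Analytes
#' detected on only one side are assigned by `single_side_policy`:
#' detected only after treatment counts as increased, only before as
#' decreased (the default), or they can be ignored.
#'
#' @param before,after Named numeric vectors of positive abundances.
#' @param fold Fold-change threshold (strict inequality; default 2).
#' @param single_side_policy `"assign"` (default) or `"ignore"`.
#' @return List with character vectors `increased` and `decreased`.
#' @export
fold_change_filter <- function(before, after, fold = 2,
                               single_side_policy = c("assign", "ignore")) {
  single_side_policy <- match.arg(single_side_policy)
  if (fold < 1) stop("'fold' must be >= 1")
  if (any(before <= 0) || any(after <= 0))
    stop("abundances must be strictly positive")
  shared <- intersect(names(before), names(after))
  ratio <- after[shared] / before[shared]
  increased <- shared[ratio > fold]
  decreased <- shared[1 / ratio > fold]
  if (single_side_policy == "assign") {
    increased <- c(increased, setdiff(names(after), names(before)))
    decreased <- c(decreased, setdiff(names(before), names(after)))
  }
  list(increased = sort(unique(increased)),
       decreased = sort(unique(decreased)))
}

#' Write differential-expression results
#'
#' @param de Data frame from [moderated_two_group_test()] or
#'   [welch_two_group_test()].
#' @param path Output TSV path (`gene  log2fc  t  p  direction`).
#' @return `path`, invisibly.
#' @export
write_de_results <- function(de, path) {
  out <- de[, c("gene", "log2fc", "t_stat", "p_value", "direction")]
  names(out) <- c("gene", "log2fc", "t", "p", "direction")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
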