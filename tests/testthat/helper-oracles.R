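# Independent oracles used to validate the implementation.  Each one is
# a deliberately naive/brute-force computation kept structurally
# different from the code path it checks.

# mean-of-sorted quantile normalization with explicit tie averaging
oracle_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    res <- numeric(length(col))
    for (i in seq_along(col)) {
      tied_positions <- which(sort(col) == col[i])
      res[i] <- mean(ref[tied_positions])
    }
    out[, j] <- res
  }
  out
}

# literal step-up BH: q_(i) = min_{j >= i} m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# codon walk over explicit triplets
oracle_codon_scan <- function(seq, cds_start, intron_start, intron_end) {
  chars <- strsplit(seq, "")[[1]]
  n_stops <- 0L
  first <- NA_integer_
  off <- cds_start
  while (off + 2 < length(chars)) {
    codon <- paste(chars[(off + 1):(off + 3)], collapse = "")
    overlaps <- length(intersect(seq(off, off + 2),
                                 seq(intron_start, intron_end - 1))) > 0
    if (codon %in% c("TAA", "TAG", "TGA") && overlaps) {
      n_stops <- n_stops + 1L
      if (is.na(first)) first <- off
    }
    off <- off + 3
  }
  list(n_stops = n_stops, first = first)
}

# brute-force recurrence matcher: pairwise field comparison, no hashing
oracle_recurrent <- function(events_by_sample, min_fraction) {
  all_ev <- do.call(rbind, lapply(names(events_by_sample), function(s) {
    ev <- events_by_sample[[s]]
    if (nrow(ev) == 0) return(NULL)
    ev$sample <- s
    ev
  }))
  n_total <- length(events_by_sample)
  need <- max(1, ceiling(min_fraction * n_total))
  if (is.null(all_ev)) return(list())
  all_ev <- all_ev[all_ev$inc_diff != 0, , drop = FALSE]
  n <- nrow(all_ev)
  if (n == 0) return(list())
  # pairwise comparison of every identity field (no hashing/keying)
  same <- outer(all_ev$event_type, all_ev$event_type, "==") &
    outer(all_ev$chrom, all_ev$chrom, "==") &
    outer(all_ev$strand, all_ev$strand, "==") &
    outer(all_ev$coords, all_ev$coords, "==") &
    outer(sign(all_ev$inc_diff), sign(all_ev$inc_diff), "==")
  seen <- rep(FALSE, n)
  out <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    grp <- which(same[i, ])
    seen[grp] <- TRUE
    samples <- unique(all_ev$sample[grp])
    if (length(samples) >= need) {
      out[[length(out) + 1]] <- list(
        event_type = all_ev$event_type[i], chrom = all_ev$chrom[i],
        strand = all_ev$strand[i], coords = all_ev$coords[i],
        sign = sign(all_ev$inc_diff[i]),
        n_samples = length(samples))
    }
  }
  out
}

# hypergeometric upper tail by direct summation of the pmf
oracle_hyper_tail <- function(N, K, n, k) {
  x <- k:min(K, n)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# random splice-event table with a small key space (forces recurrence)
random_splice_events <- function(n_events, sample_id, key_pool) {
  idx <- sample(nrow(key_pool), n_events, replace = TRUE)
  data.frame(
    event_type = key_pool$event_type[idx],
    gene = "GX", chrom = key_pool$chrom[idx],
    strand = key_pool$strand[idx], coords = key_pool$coords[idx],
    inc_level_control = 0.5, inc_level_treated = 0.6,
    inc_diff = key_pool$sign[idx] * runif(n_events, 0.06, 0.5),
    fdr = runif(n_events, 0, 0.049), sample_id = sample_id,
    stringsAsFactors = FALSE)
}

make_key_pool <- function(n_keys) {
  data.frame(
    event_type = sample(c("SE", "RI", "A5SS", "A3SS", "MXE"), n_keys,
                        replace = TRUE),
    chrom = paste0("chr", sample(1:5, n_keys, replace = TRUE)),
    strand = sample(c("+", "-"), n_keys, replace = TRUE),
    coords = vapply(seq_len(n_keys), function(i)
      paste(sort(sample.int(1e6, 6)), collapse = ":"), character(1)),
    sign = sample(c(-1, 1), n_keys, replace = TRUE),
    stringsAsFactors = FALSE)
}

# small two-group dataset builder
make_dataset <- function(values, n_ctrl, n_trt, id = "ds1") {
  samples <- c(paste0("c", seq_len(n_ctrl)), paste0("t", seq_len(n_trt)))
  colnames(values) <- samples
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  groups <- stats::setNames(rep(c("control", "treated"),
                                c(n_ctrl, n_trt)), samples)
  expression_dataset(id, values, groups)
}
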