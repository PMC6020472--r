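# Differential alternative splicing: rMATS-style table parsing,
# significance filtering, cross-sample event matching and recurrence.
#
# Event identity is purely positional: (type, chrom, strand, the type's
# full defining coordinate tuple) plus the sign of the inclusion-level
# difference.  Gene symbols are not part of the key, which keeps matching
# robust to annotation drift.  Coordinates follow the source dialect:
# 0-based, half-open.

.rmats_coord_cols <- list(
  SE   = c("exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
  RI   = c("riExonStart_0base", "riExonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
  A5SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"),
  A3SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"),
  MXE  = c("1stExonStart_0base", "1stExonEnd", "2ndExonStart", "2ndExonEnd",
           "upstreamES", "upstreamEE", "downstreamES", "downstreamEE")
)

.mean_inc <- function(x) {
  vapply(strsplit(as.character(x), ","), function(v) {
    v <- suppressWarnings(as.numeric(v))
    mean(v[!is.na(v)])
  }, numeric(1))
}

#' Read rMATS-style differential-splicing tables for one sample
#'
#' Scans a directory for per-event-type files (`SE.MATS.JC.txt`-style
#' names; the glob is configurable), averages the comma-separated
#' per-replicate inclusion levels per condition, and re-signs the
#' inclusion-level difference so that positive always means higher
#' inclusion in the treated condition, regardless of which group the
#' caller put in the file's "sample 1" slot.
#'
#' @param dir Directory containing the per-type tab-separated files.
#' @param sample_id Label attached to every event (one comparison =
#'   one sample unit for recurrence counting).
#' @param sample1 Which condition the file's `IncLevel1` column holds:
#'   `"treated"` (default rMATS usage in a treated-vs-control run) or
#'   `"control"`.
#' @param pattern Regular expression selecting event files; the leading
#'   token of the file name must be the event type.
#' @return Data frame of splice events: `event_type`, `gene`, `chrom`,
#'   `strand`, `coords` (colon-joined defining tuple), `inc_level_control`,
#'   `inc_level_treated`, `inc_diff` (treated minus control), `fdr`,
#'   `sample_id`.  Unknown event-type files are skipped with a warning.
#' @export
read_rmats_tables <- function(dir, sample_id,
                              sample1 = c("treated", "control"),
                              pattern = "\\.MATS\\..*\\.txt$") {
  sample1 <- match.arg(sample1)
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  out <- list()
  for (f in files) {
    type <- sub("\\..*$", "", basename(f))
    if (!type %in% names(.rmats_coord_cols)) {
      warning("skipping unrecognized event-type file: ", basename(f))
      next
    }
    tab <- utils::read.delim(f, header = TRUE, sep = "\t",
                             check.names = FALSE,
                             colClasses = "character")
    if (nrow(tab) == 0) next
    cols <- .rmats_coord_cols[[type]]
    need <- c(cols, "chr", "strand", "IncLevel1", "IncLevel2",
              "IncLevelDifference", "FDR")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("file ", basename(f), " lacks column(s): ",
           paste(miss, collapse = ", "))
    coord_mat <- suppressWarnings(
      vapply(cols, function(cl) as.numeric(tab[[cl]]), numeric(nrow(tab))))
    coord_mat <- matrix(coord_mat, nrow = nrow(tab))
    bad <- which(is.na(coord_mat) | coord_mat != floor(coord_mat),
                 arr.ind = TRUE)
    if (nrow(bad))
      stop("malformed coordinate in ", basename(f), " line ",
           bad[1, 1] + 1L, " (column ", cols[bad[1, 2]], ")")
    inc1 <- .mean_inc(tab$IncLevel1)
    inc2 <- .mean_inc(tab$IncLevel2)
    diff <- suppressWarnings(as.numeric(tab$IncLevelDifference))
    fdr <- suppressWarnings(as.numeric(tab$FDR))
    if (sample1 == "treated") {
      trt <- inc1; ctl <- inc2
    } else {
      trt <- inc2; ctl <- inc1
      diff <- -diff
    }
    gene <- if ("geneSymbol" %in% names(tab)) tab$geneSymbol
      else if ("GeneID" %in% names(tab)) tab$GeneID else NA_character_
    out[[length(out) + 1L]] <- data.frame(
      event_type = type, gene = gene, chrom = tab$chr,
      strand = tab$strand,
      coords = apply(coord_mat, 1, paste, collapse = ":"),
      inc_level_control = ctl, inc_level_treated = trt,
      inc_diff = diff, fdr = fdr, sample_id = sample_id,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(event_type = character(), gene = character(),
                      chrom = character(), strand = character(),
                      coords = character(), inc_level_control = numeric(),
                      inc_level_treated = numeric(), inc_diff = numeric(),
                      fdr = numeric(), sample_id = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Filter splice events by significance
#'
#' Keeps events with `fdr < fdr_max` and `|inc_diff| > min_abs_diff`
#' (both strict: an inclusion-level difference of exactly 5% on the
#' \[0, 1\] proportion scale is dropped).
#'
#' @param events Data frame of splice events (see [read_rmats_tables()]).
#' @param fdr_max FDR cutoff (default 0.05).
#' @param min_abs_diff Minimum absolute inclusion-level difference on the
#'   \[0, 1\] scale (default 0.05, i.e. 5%).
#' @return The filtered event data frame.
#' @export
filter_significant <- function(events, fdr_max = 0.05,
                               min_abs_diff = 0.05) {
  events[events$fdr < fdr_max & abs(events$inc_diff) > min_abs_diff, ,
         drop = FALSE]
}

#' Event identity key
#'
#' Events are considered identical when they share type, chromosome,
#' strand, the full defining coordinate tuple, and the sign of the
#' inclusion-level difference.  Zero-difference events have no key.
#'
#' @param events Data frame of splice events.
#' @return Character vector of keys (`NA` for zero-difference events).
#' @export
event_key <- function(events) {
  sgn <- ifelse(events$inc_diff > 0, "+1",
                ifelse(events$inc_diff < 0, "-1", NA_character_))
  ifelse(is.na(sgn), NA_character_,
         paste(events$event_type, events$chrom, events$strand,
               events$coords, sgn, sep = "|"))
}

#' Find events recurring across samples
#'
#' Groups events by identity key, counting each key at most once per
#' sample, and keeps keys present in at least
#' `ceiling(min_fraction * n_samples)` samples ("at least half" uses the
#' ceiling for odd counts: 9 of 17 qualifies).
#'
#' @param events_by_sample Named list (sample id -> event data frame) or
#'   a single data frame carrying a `sample_id` column.  The total sample
#'   count is the number of list entries (or distinct `sample_id`s).
#' @param min_fraction Minimum fraction of samples (default 0.5).
#' @return Data frame of recurrent events: `event_type`, `chrom`,
#'   `strand`, `coords`, `sign` (+1/-1), `n_samples`, `sample_ids`
#'   (comma-joined), `mean_inc_diff` (mean over contributing samples,
#'   averaging within a sample first).
#' @export
find_recurrent <- function(events_by_sample, min_fraction = 0.5) {
  if (is.data.frame(events_by_sample))
    events_by_sample <- split(events_by_sample,
                              events_by_sample$sample_id)
  n_total <- length(events_by_sample)
  if (n_total < 1) stop("need at least one sample")
  per_sample <- lapply(names(events_by_sample), function(sid) {
    ev <- events_by_sample[[sid]]
    if (nrow(ev) == 0) return(NULL)
    key <- event_key(ev)
    ok <- !is.na(key)
    if (!any(ok)) return(NULL)
    agg <- tapply(ev$inc_diff[ok], key[ok], mean)   # once per sample
    data.frame(key = names(agg), sample = sid,
               inc_diff = as.numeric(agg), stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, per_sample)
  empty <- data.frame(event_type = character(), chrom = character(),
                      strand = character(), coords = character(),
                      sign = integer(), n_samples = integer(),
                      sample_ids = character(), mean_inc_diff = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(long) || nrow(long) == 0) return(empty)
  need <- max(1L, ceiling(min_fraction * n_total))
  counts <- table(long$key)
  keep <- names(counts)[counts >= need]
  if (length(keep) == 0) return(empty)
  rows <- lapply(keep, function(k) {
    sub <- long[long$key == k, ]
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(event_type = parts[1], chrom = parts[2], strand = parts[3],
               coords = parts[4], sign = as.integer(parts[5]),
               n_samples = nrow(sub),
               sample_ids = paste(sort(sub$sample), collapse = ","),
               mean_inc_diff = mean(sub$inc_diff),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$n_samples, out$event_type, out$chrom, out$coords), ,
      drop = FALSE]
}

#' Summarize event-type composition and intron-retention directionality
#'
#' @param events Data frame of splice events (with `inc_diff`) or of
#'   recurrent events (with `mean_inc_diff`/`sign`).
#' @return List with `type_counts` (named vector over SE, A5SS, A3SS, RI,
#'   MXE) and `ri_direction`: `n_positive`, `n_negative`,
#'   `fraction_positive` (NA when there are no signed RI events).  For
#'   intron retention a positive difference means the intron is included
#'   more after treatment.
#' @export
type_summary <- function(events) {
  types <- c("SE", "A5SS", "A3SS", "RI", "MXE")
  tc <- table(factor(events$event_type, levels = types))
  diff_col <- if ("inc_diff" %in% names(events)) events$inc_diff
    else events$mean_inc_diff
  ri <- events$event_type == "RI"
  npos <- sum(ri & diff_col > 0)
  nneg <- sum(ri & diff_col < 0)
  list(type_counts = stats::setNames(as.integer(tc), types),
       ri_direction = list(
         n_positive = npos, n_negative = nneg,
         fraction_positive = if (npos + nneg > 0) npos / (npos + nneg)
           else NA_real_))
}

#' Write recurrent events
#'
#' @param recurrent Data frame from [find_recurrent()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_recurrent_events <- function(recurrent, path) {
  cols <- c("event_type", "chrom", "strand", "coords", "sign",
            "n_samples", "mean_inc_diff")
  utils::write.table(recurrent[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
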