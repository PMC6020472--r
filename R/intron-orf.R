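# Retained-intron stop-codon scan.
#
# Given the retained-form transcript sequence, the annotated reading
# frame (CDS start) and the interval occupied by the retained intron,
# decide whether retention introduces in-frame premature termination
# codons (PTCs), i.e. whether the retained transcript can still encode a
# full-length protein.

.stop_codons <- c("TAA", "TAG", "TGA")

#' Construct a transcript model for the stop-codon scan
#'
#' @param transcript_id Unique identifier.
#' @param spliced_seq Retained-form mRNA sequence, uppercase ACGT only
#'   (ambiguity codes are rejected rather than guessed).
#' @param cds_start 0-based offset of the first base of the start codon.
#' @param intron_start,intron_end 0-based half-open interval of the
#'   retained intron within `spliced_seq`; must begin downstream of
#'   `cds_start`.
#' @return An object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, spliced_seq, cds_start,
                             intron_start, intron_end) {
  spliced_seq <- as.character(spliced_seq)
  if (grepl("[^ACGT]", spliced_seq))
    stop("sequence of '", transcript_id,
         "' contains characters outside uppercase ACGT")
  n <- nchar(spliced_seq)
  if (cds_start < 0 || cds_start >= n) stop("cds_start out of bounds")
  if (intron_start < 0 || intron_end > n || intron_start >= intron_end)
    stop("invalid intron interval [", intron_start, ", ", intron_end, ")")
  if (intron_start <= cds_start)
    stop("retained intron must begin downstream of the CDS start")
  structure(list(transcript_id = as.character(transcript_id),
                 spliced_seq = spliced_seq, cds_start = as.integer(cds_start),
                 intron_start = as.integer(intron_start),
                 intron_end = as.integer(intron_end)),
            class = "TranscriptModel")
}

#' Scan a retained intron for in-frame stop codons
#'
#' Walks codons in the frame fixed by the CDS start.  A codon counts as
#' an intron-introduced stop iff it is TAA/TAG/TGA and overlaps the
#' intron interval by at least one base -- a stop straddling the
#' exon-intron boundary exists only because of retention, so it is
#' attributed to the intron.  All in-frame stops overlapping the intron
#' are tallied; `first_stop_offset` is the leftmost one.
#'
#' @param model A [transcript_model()].
#' @return List of class `StopScanResult`: `transcript_id`,
#'   `n_inframe_stops_in_intron`, `first_stop_offset` (0-based, `NA` if
#'   none), `ptc_flag`.
#' @export
scan_retained_intron <- function(model) {
  stopifnot(inherits(model, "TranscriptModel"))
  seq <- model$spliced_seq
  n <- nchar(seq)
  n_stops <- 0L
  first <- NA_integer_
  # codon starts in frame; anything starting at or beyond intron_end
  # cannot overlap the intron
  off <- model$cds_start
  while (off + 3L <= n && off < model$intron_end) {
    codon <- substr(seq, off + 1L, off + 3L)
    if (codon %in% .stop_codons &&
        off < model$intron_end && off + 3L > model$intron_start) {
      n_stops <- n_stops + 1L
      if (is.na(first)) first <- off
    }
    off <- off + 3L
  }
  structure(list(transcript_id = model$transcript_id,
                 n_inframe_stops_in_intron = n_stops,
                 first_stop_offset = first,
                 ptc_flag = n_stops >= 1L),
            class = "StopScanResult")
}

#' Scan many transcripts and summarize the PTC fraction
#'
#' @param models List of [transcript_model()] objects with unique IDs.
#' @return List with `results` (data frame: `transcript_id`, `n_stops`,
#'   `first_stop_offset`, `ptc`) and `fraction_ptc` (`NA` for empty
#'   input).
#' @export
batch_scan <- function(models) {
  ids <- vapply(models, `[[`, character(1), "transcript_id")
  if (anyDuplicated(ids))
    stop("duplicate transcript_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(models) == 0) {
    return(list(results = data.frame(transcript_id = character(),
                                     n_stops = integer(),
                                     first_stop_offset = integer(),
                                     ptc = logical()),
                fraction_ptc = NA_real_))
  }
  res <- lapply(models, scan_retained_intron)
  df <- data.frame(
    transcript_id = vapply(res, `[[`, character(1), "transcript_id"),
    n_stops = vapply(res, `[[`, integer(1), "n_inframe_stops_in_intron"),
    first_stop_offset = vapply(res, `[[`, integer(1), "first_stop_offset"),
    ptc = vapply(res, `[[`, logical(1), "ptc_flag"),
    stringsAsFactors = FALSE)
  list(results = df, fraction_ptc = mean(df$ptc))
}

#' Read transcript models from FASTA plus annotation TSV
#'
#' The annotation table has columns
#' `transcript_id  cds_start  intron_start  intron_end` (0-based,
#' half-open), one row per transcript in the FASTA.
#'
#' @param fasta_path Path to the retained-form transcript FASTA.
#' @param annotation_path Path to the companion TSV.
#' @return List of [transcript_model()] objects.
#' @export
read_transcript_models <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ann <- utils::read.delim(annotation_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("transcript_id", "cds_start", "intron_start", "intron_end")
  if (!all(need %in% names(ann)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  missing <- setdiff(ann$transcript_id, names(seqs))
  if (length(missing))
    stop("transcript(s) absent from FASTA: ",
         paste(missing, collapse = ", "))
  lapply(seq_len(nrow(ann)), function(i) {
    transcript_model(ann$transcript_id[i],
                     as.character(seqs[[ann$transcript_id[i]]]),
                     ann$cds_start[i], ann$intron_start[i],
                     ann$intron_end[i])
  })
}

#' Write stop-scan results
#'
#' @param scan Result of [batch_scan()].
#' @param path Output TSV path
#'   (`transcript_id  n_stops  first_stop_offset  ptc`).
#' @return `path`, invisibly.
#' @export
write_stop_scan <- function(scan, path) {
  utils::write.table(scan$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
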