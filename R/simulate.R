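# Synthetic-data generators.
#
# Every input class the pipeline consumes can be generated with known
# ground truth: multi-dataset two-group expression with a planted
# direction-consistent pathway shift, time courses with planted cluster
# trends, per-sample differential-splicing tables with planted recurrent
# retained introns, codon-structured transcripts with planted in-frame
# stops, and a TF-binding fixture with planted co-regulated pairs.  All
# generators are deterministic given their seed.

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
    else if (exists(".Random.seed", .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  force(expr)
}

#' Simulate a multi-dataset two-group expression collection
#'
#' Each dataset draws per-gene baselines from
#' `Normal(platform_shift, 1) * platform_scale` (platforms differ in
#' location and scale), adds the planted log2 shift `delta` to treated
#' samples of planted genes, and adds i.i.d. Gaussian measurement noise
#' on the log2 scale.  Ground-truth labels record each gene's true
#' direction.
#'
#' @param seed Integer seed.
#' @param n_datasets Number of studies (default 3).
#' @param genes_total Genes per study (default 2000; all studies share
#'   the same harmonized gene IDs).
#' @param planted Named list of planted gene sets, each a list with
#'   `size` and `delta` (log2 shift; sign = direction).  Default: one
#'   100-gene "spliceosome" set shifted by -1 (halved expression).
#' @param samples_per_group Samples in each of control/treated
#'   (default 3, a typical per-study size in public two-group designs).
#' @param noise_sd Measurement noise sd on the log2 scale (default 1).
#' @param platform_shift,platform_scale Per-dataset location/scale
#'   (defaults: shifts 7, 7.5, 8, ...; scales 1, 1.1, 1.2, ... --
#'   mildly different platforms).
#' @return List with `datasets` (named list of [expression_dataset()])
#'   and `truth` (data frame `gene`, `planted_set` ("" for null genes),
#'   `true_direction`).
#' @export
gen_expression_multiset <- function(seed, n_datasets = 3,
                                    genes_total = 2000,
                                    planted = list(
                                      spliceosome = list(size = 100,
                                                         delta = -1)),
                                    samples_per_group = 3,
                                    noise_sd = 1,
                                    platform_shift = NULL,
                                    platform_scale = NULL) {
  total_planted <- sum(vapply(planted, `[[`, numeric(1), "size"))
  if (total_planted > genes_total)
    stop("planted sets larger than genes_total")
  if (is.null(platform_shift))
    platform_shift <- 7 + 0.5 * (seq_len(n_datasets) - 1)
  if (is.null(platform_scale))
    platform_scale <- 1 + 0.1 * (seq_len(n_datasets) - 1)
  genes <- sprintf("G%05d", seq_len(genes_total))
  set_of <- rep("", genes_total)
  delta_of <- rep(0, genes_total)
  at <- 1
  for (nm in names(planted)) {
    sz <- planted[[nm]]$size
    set_of[at:(at + sz - 1)] <- nm
    delta_of[at:(at + sz - 1)] <- planted[[nm]]$delta
    at <- at + sz
  }
  .with_seed(seed, {
    datasets <- lapply(seq_len(n_datasets), function(d) {
      id <- sprintf("synthstudy%02d", d)
      n <- samples_per_group
      samples <- c(sprintf("%s_ctrl%d", id, seq_len(n)),
                   sprintf("%s_trt%d", id, seq_len(n)))
      groups <- stats::setNames(rep(c("control", "treated"), each = n),
                                samples)
      baseline <- stats::rnorm(genes_total, platform_shift[d], 1) *
        platform_scale[d]
      vals <- matrix(baseline, genes_total, 2 * n) +
        matrix(stats::rnorm(genes_total * 2 * n, 0, noise_sd),
               genes_total, 2 * n)
      vals[, (n + 1):(2 * n)] <- vals[, (n + 1):(2 * n)] + delta_of
      dimnames(vals) <- list(genes, samples)
      expression_dataset(id, vals, groups)
    })
    names(datasets) <- vapply(datasets, `[[`, character(1), "dataset_id")
    truth <- data.frame(
      gene = genes, planted_set = set_of,
      true_direction = ifelse(delta_of > 0, "up",
                              ifelse(delta_of < 0, "down", "null")),
      stringsAsFactors = FALSE)
    list(datasets = datasets, truth = truth)
  })
}

#' Simulate a z-scored expression time course with planted clusters
#'
#' Each cluster has a template trajectory on the z scale (defaults: a
#' gradually decreasing trend, its mirror image, and a flat profile);
#' genes are the template plus Gaussian noise, then row z-scored.
#'
#' @param seed Integer seed.
#' @param timepoints Hours (default 0, 6, 12, 24 -- four timepoints, the
#'   minimum the trend analysis assumes).
#' @param templates Named list of numeric template trajectories, one per
#'   cluster, each of length `length(timepoints)`.
#' @param sizes Integer vector of genes per cluster (recycled).
#' @param noise_sd Per-timepoint noise sd before z-scoring
#'   (default 0.3).
#' @return List with `data` (a `TimeSeriesMatrix`) and `labels` (named
#'   integer vector of true cluster indices).
#' @export
gen_timecourse <- function(seed, timepoints = c(0, 6, 12, 24),
                           templates = NULL, sizes = 100,
                           noise_sd = 0.3) {
  tn <- length(timepoints)
  if (tn < 4) stop("need at least 4 timepoints")
  if (is.null(templates)) {
    dec <- seq(1, -1, length.out = tn)
    templates <- list(decreasing = dec, increasing = -dec,
                      flat_wiggle = c(rep(0, tn - 1), 0.2))
  }
  k <- length(templates)
  sizes <- rep_len(sizes, k)
  .with_seed(seed, {
    rows <- list(); labels <- integer(0)
    for (j in seq_len(k)) {
      block <- matrix(rep(templates[[j]], each = sizes[j]), sizes[j], tn) +
        matrix(stats::rnorm(sizes[j] * tn, 0, noise_sd), sizes[j], tn)
      rows[[j]] <- block
      labels <- c(labels, rep(j, sizes[j]))
    }
    vals <- do.call(rbind, rows)
    genes <- sprintf("T%04d", seq_len(nrow(vals)))
    dimnames(vals) <- list(genes, paste0("t", timepoints))
    data <- structure(list(genes = genes, timepoints = timepoints,
                           values = zscore_rows(vals)),
                      class = "TimeSeriesMatrix")
    list(data = data, labels = stats::setNames(labels, genes))
  })
}

.codon_pool <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T")),
                             1, paste, collapse = ""),
                       c("TAA", "TAG", "TGA"))

.random_codons <- function(n) {
  paste(sample(.codon_pool, n, replace = TRUE), collapse = "")
}

#' Simulate retained-intron transcripts with planted stop counts
#'
#' Builds codon-structured CDS sequences in which the retained intron is
#' frame-aligned and contains exactly the requested number of in-frame
#' stop codons (all other codons are drawn from the 61 non-stop codons).
#'
#' @param seed Integer seed.
#' @param stop_counts Integer vector: planted in-frame stops per
#'   transcript (default 0:3 recycled over 12 transcripts).
#' @param n_transcripts Number of transcripts.
#' @param intron_codons Intron length in codons (default 20; must exceed
#'   `max(stop_counts)`).
#' @return List with `models` (list of [transcript_model()]) and `truth`
#'   (data frame `transcript_id`, `n_stops_planted`).
#' @export
gen_transcripts <- function(seed, stop_counts = 0:3, n_transcripts = 12,
                            intron_codons = 20) {
  stop_counts <- rep_len(stop_counts, n_transcripts)
  if (max(stop_counts) >= intron_codons)
    stop("intron_codons must exceed the largest planted stop count")
  .with_seed(seed, {
    models <- vector("list", n_transcripts)
    for (i in seq_len(n_transcripts)) {
      id <- sprintf("TX%03d", i)
      utr5 <- .random_codons(sample(1:4, 1))   # frame offset from 0
      exon1_codons <- sample(5:15, 1)
      exon1 <- paste0("ATG", .random_codons(exon1_codons))
      intron_cod <- sample(.codon_pool, intron_codons, replace = TRUE)
      if (stop_counts[i] > 0) {
        where <- sample(intron_codons, stop_counts[i])
        intron_cod[where] <- sample(c("TAA", "TAG", "TGA"),
                                    stop_counts[i], replace = TRUE)
      }
      intron <- paste(intron_cod, collapse = "")
      exon2 <- paste0(.random_codons(sample(5:15, 1)), "TAA")
      seq <- paste0(utr5, exon1, intron, exon2)
      cds_start <- nchar(utr5)
      intron_start <- cds_start + nchar(exon1)
      models[[i]] <- transcript_model(id, seq, cds_start, intron_start,
                                      intron_start + nchar(intron))
    }
    truth <- data.frame(
      transcript_id = vapply(models, `[[`, character(1), "transcript_id"),
      n_stops_planted = stop_counts, stringsAsFactors = FALSE)
    list(models = models, truth = truth)
  })
}

#' Write transcript models as FASTA plus annotation TSV
#'
#' @param models List of [transcript_model()] objects.
#' @param fasta_path,annotation_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_transcript_models <- function(models, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(models, `[[`, character(1), "spliced_seq"))
  names(seqs) <- vapply(models, `[[`, character(1), "transcript_id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  ann <- data.frame(
    transcript_id = names(seqs),
    cds_start = vapply(models, `[[`, integer(1), "cds_start"),
    intron_start = vapply(models, `[[`, integer(1), "intron_start"),
    intron_end = vapply(models, `[[`, integer(1), "intron_end"))
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fasta_path)
}

.rmats_header <- function(type) {
  c("ID", "GeneID", "geneSymbol", "chr", "strand",
    .rmats_coord_cols[[type]],
    "IncLevel1", "IncLevel2", "IncLevelDifference", "FDR")
}

.rmats_row <- function(type, gene, chrom, strand, coords, inc_trt,
                       inc_ctl, fdr, id) {
  # files are written in the sample1 = treated orientation
  c(id, gene, gene, chrom, strand, as.character(coords),
    paste(sprintf("%.4f", inc_trt), collapse = ","),
    paste(sprintf("%.4f", inc_ctl), collapse = ","),
    sprintf("%.4f", mean(inc_trt) - mean(inc_ctl)), sprintf("%.6g", fdr))
}

.random_event_coords <- function(type) {
  k <- length(.rmats_coord_cols[[type]])
  start <- sample.int(89000000L, 1) + 1000000L
  sort(start + cumsum(sample(100:5000, k, replace = TRUE)))
}

#' Simulate per-sample rMATS-style differential-splicing tables
#'
#' Writes one sub-directory per sample with per-type event files.
#' Planted events appear with a fixed sign, `FDR < 0.05` and
#' `|IncLevelDifference|` drawn Uniform(0.1, 0.5) (clear of the 5%
#' filter boundary) in exactly `ceiling(fraction * n_samples)` samples;
#' background events get sample-specific random coordinates, roughly
#' half of them failing the significance filter.  The planted default
#' mirrors the structure seen after therapy: retained introns mostly
#' gain inclusion (positive sign), exon skipping is sign-balanced.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created).
#' @param n_samples Number of comparison samples (default 18).
#' @param planted Data frame with columns `event_type`, `sign` (+1/-1),
#'   `fraction`; default 12 events (6 RI: 5 positive/1 negative; 4 SE
#'   balanced; 2 A5SS) with fractions 0.5-0.9.
#' @param background_per_sample Background events per sample per run
#'   (default 120, spread over the five types).
#' @return List with `dir`, `samples`, and `truth` (data frame:
#'   `key`, `event_type`, `sign`, `n_samples_planted`,
#'   `sample_ids` comma-joined).
#' @export
gen_splice_tables <- function(seed, dir, n_samples = 18, planted = NULL,
                              background_per_sample = 120) {
  if (is.null(planted)) {
    planted <- data.frame(
      event_type = c(rep("RI", 6), rep("SE", 4), rep("A5SS", 2)),
      sign = c(1, 1, 1, 1, 1, -1, 1, -1, 1, -1, 1, -1),
      fraction = rep(c(0.9, 0.7, 0.5), 4),
      stringsAsFactors = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- sprintf("sample%02d", seq_len(n_samples))
  types <- names(.rmats_coord_cols)
  .with_seed(seed, {
    planted$chrom <- if (nrow(planted))
      paste0("chr", sample(1:22, nrow(planted), replace = TRUE))
      else character(0)
    planted$strand <- sample(c("+", "-"), nrow(planted), replace = TRUE)
    planted$coords <- vapply(planted$event_type, function(tt)
      paste(.random_event_coords(tt), collapse = ":"), character(1))
    planted$n_target <- ceiling(planted$fraction * n_samples)
    carriers <- lapply(planted$n_target, function(k)
      sort(sample(n_samples, k)))
    rows_by_sample_type <- list()
    for (s in seq_len(n_samples)) {
      for (tt in types) rows_by_sample_type[[paste(s, tt)]] <- list()
    }
    # planted events
    for (i in seq_len(nrow(planted))) {
      for (s in carriers[[i]]) {
        diff <- planted$sign[i] * stats::runif(1, 0.1, 0.5)
        ctl <- stats::runif(1, 0.25, 0.5)
        trt <- min(max(ctl + diff, 0), 1)
        key <- paste(s, planted$event_type[i])
        rows_by_sample_type[[key]][[length(rows_by_sample_type[[key]]) + 1]] <-
          .rmats_row(planted$event_type[i], sprintf("PL%03d", i),
                     planted$chrom[i], planted$strand[i],
                     strsplit(planted$coords[i], ":")[[1]],
                     rep(trt, 2), rep(ctl, 2),
                     stats::runif(1, 1e-6, 0.049), id = 1000 + i)
      }
    }
    # background events: sample-specific random coordinates
    for (s in seq_len(n_samples)) {
      n_bg <- background_per_sample
      bg_types <- sample(types, n_bg, replace = TRUE)
      for (b in seq_len(n_bg)) {
        tt <- bg_types[b]
        sig <- stats::runif(1) < 0.5
        diff <- stats::runif(1, -0.6, 0.6)
        if (!sig && stats::runif(1) < 0.5) diff <- stats::runif(1, -0.04, 0.04)
        ctl <- stats::runif(1, 0.2, 0.7)
        trt <- min(max(ctl + diff, 0), 1)
        key <- paste(s, tt)
        rows_by_sample_type[[key]][[length(rows_by_sample_type[[key]]) + 1]] <-
          .rmats_row(tt, sprintf("BG%05d", b),
                     paste0("chr", sample(1:22, 1)),
                     sample(c("+", "-"), 1),
                     .random_event_coords(tt),
                     rep(trt, 2), rep(ctl, 2),
                     if (sig) stats::runif(1, 1e-6, 0.049)
                     else stats::runif(1, 0.05, 1), id = b)
      }
    }
    for (s in seq_len(n_samples)) {
      sdir <- file.path(dir, samples[s])
      dir.create(sdir, showWarnings = FALSE)
      for (tt in types) {
        rows <- rows_by_sample_type[[paste(s, tt)]]
        con <- file.path(sdir, paste0(tt, ".MATS.JC.txt"))
        lines <- c(paste(.rmats_header(tt), collapse = "\t"),
                   vapply(rows, paste, character(1), collapse = "\t"))
        writeLines(lines, con)
      }
    }
    truth <- data.frame(
      key = paste(planted$event_type, planted$chrom, planted$strand,
                  planted$coords,
                  ifelse(planted$sign > 0, "+1", "-1"), sep = "|"),
      event_type = planted$event_type, sign = planted$sign,
      n_samples_planted = planted$n_target,
      sample_ids = vapply(carriers, function(ix)
        paste(samples[ix], collapse = ","), character(1)),
      stringsAsFactors = FALSE)
    list(dir = dir, samples = samples, truth = truth)
  })
}

#' Simulate the TF co-regulation fixture
#'
#' Plants co-expressed (splicing gene, mitotic gene) pairs driven by a
#' shared latent factor, and gives each planted TF promoter peaks at
#' both members of its pair.  A pair (and therefore its TF) is
#' correlated only in the datasets it is planted in, so TFs planted in
#' every dataset are recoverable as "common" while TFs planted in a
#' strict subset are not.
#'
#' @param seed Integer seed.
#' @param n_datasets Number of datasets (default 4, e.g. one drug class).
#' @param n_samples Samples per dataset (default 20; rank correlations
#'   need a reasonable sample count before an FDR-corrected 0.7
#'   threshold is reliably reachable by true pairs).
#' @param n_splicing,n_mitotic Sizes of the two candidate gene sets
#'   (default 10 each).
#' @param pair_noise_sd Noise around the shared latent factor
#'   (default 0.15; pairs correlate near 1).
#' @param window Promoter half-width used when placing peaks
#'   (default 2000).
#' @return List with `datasets`, `splicing_genes`, `mitotic_genes`,
#'   `peaks`, `tss`, `truth` (list: `common_tfs`, `partial_tfs`).
#' @export
gen_tf_fixture <- function(seed, n_datasets = 4, n_samples = 20,
                           n_splicing = 10, n_mitotic = 10,
                           pair_noise_sd = 0.15, window = 2000) {
  sg <- sprintf("SPL%02d", seq_len(n_splicing))
  mg <- sprintf("MIT%02d", seq_len(n_mitotic))
  genes <- c(sg, mg)
  # planted structure: pair 1 in all datasets (TF_ALL), pair 2 in all
  # but the last dataset (TF_PART); TF_NONE binds unpaired genes
  pair_all <- c(sg[1], mg[1])
  pair_part <- c(sg[2], mg[2])
  .with_seed(seed, {
    datasets <- lapply(seq_len(n_datasets), function(d) {
      id <- sprintf("tfstudy%02d", d)
      samples <- sprintf("%s_s%02d", id, seq_len(n_samples))
      vals <- matrix(stats::rnorm(length(genes) * n_samples),
                     length(genes), n_samples,
                     dimnames = list(genes, samples))
      latent <- stats::rnorm(n_samples)
      vals[pair_all[1], ] <- latent +
        stats::rnorm(n_samples, 0, pair_noise_sd)
      vals[pair_all[2], ] <- latent +
        stats::rnorm(n_samples, 0, pair_noise_sd)
      if (d < n_datasets) {
        latent2 <- stats::rnorm(n_samples)
        vals[pair_part[1], ] <- latent2 +
          stats::rnorm(n_samples, 0, pair_noise_sd)
        vals[pair_part[2], ] <- latent2 +
          stats::rnorm(n_samples, 0, pair_noise_sd)
      }
      groups <- stats::setNames(rep(c("control", "treated"),
                                    length.out = n_samples), samples)
      expression_dataset(id, vals, groups)
    })
    names(datasets) <- vapply(datasets, `[[`, character(1), "dataset_id")
    tss <- data.frame(gene = genes, chrom = "chr1", strand = "+",
                      tss = 100000L * seq_along(genes),
                      stringsAsFactors = FALSE)
    peak_at <- function(tf, gene) {
      pos <- tss$tss[tss$gene == gene]
      data.frame(chrom = "chr1", start = pos - 50L, end = pos + 50L,
                 tf = tf, stringsAsFactors = FALSE)
    }
    peaks <- rbind(
      peak_at("TF_ALL", pair_all[1]), peak_at("TF_ALL", pair_all[2]),
      peak_at("TF_PART", pair_part[1]), peak_at("TF_PART", pair_part[2]),
      peak_at("TF_NONE", sg[5]), peak_at("TF_NONE", sg[6]))
    list(datasets = datasets, splicing_genes = sg, mitotic_genes = mg,
         peaks = peaks, tss = tss,
         truth = list(common_tfs = "TF_ALL", partial_tfs = "TF_PART"))
  })
}
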