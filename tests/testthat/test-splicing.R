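write_ri_file <- function(dir, inc1 = "0.5,0.7", inc2 = "0.2,0.2",
                          diff = "0.4", fdr = "0.01",
                          coords = c(100, 200, 50, 100, 200, 250)) {
  header <- c("ID", "GeneID", "geneSymbol", "chr", "strand",
              "riExonStart_0base", "riExonEnd", "upstreamES",
              "upstreamEE", "downstreamES", "downstreamEE",
              "IncLevel1", "IncLevel2", "IncLevelDifference", "FDR")
  row <- c("1", "G1", "G1", "chr1", "+", as.character(coords),
           inc1, inc2, diff, fdr)
  writeLines(c(paste(header, collapse = "\t"),
               paste(row, collapse = "\t")),
             file.path(dir, "RI.MATS.JC.txt"))
}

test_that("rMATS parsing averages replicates and re-signs by orientation", {
  d <- tempfile(); dir.create(d)
  write_ri_file(d)
  ev <- read_rmats_tables(d, "s1", sample1 = "treated")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$inc_level_treated, 0.6)
  expect_equal(ev$inc_level_control, 0.2)
  expect_equal(ev$inc_diff, 0.4)
  expect_identical(ev$coords, "100:200:50:100:200:250")

  flipped <- read_rmats_tables(d, "s1", sample1 = "control")
  expect_equal(flipped$inc_diff, -0.4)
  expect_equal(flipped$inc_level_treated, 0.2)
})

test_that("unknown event-type files are skipped, bad coordinates fatal", {
  d <- tempfile(); dir.create(d)
  writeLines("nonsense", file.path(d, "XYZ.MATS.JC.txt"))
  expect_warning(ev <- read_rmats_tables(d, "s1"), "XYZ")
  expect_equal(nrow(ev), 0)

  d2 <- tempfile(); dir.create(d2)
  write_ri_file(d2, coords = c(100, "20x", 50, 100, 200, 250))
  expect_error(read_rmats_tables(d2, "s1"), "line 2")
})

test_that("significance filter is strict at both boundaries and idempotent", {
  ev <- data.frame(event_type = "SE", gene = "G", chrom = "chr1",
                   strand = "+", coords = "1:2:3:4:5:6",
                   inc_level_control = 0.5, inc_level_treated = 0.6,
                   inc_diff = c(0.06, 0.5, -0.05, 0.2),
                   fdr = c(0.04, 0.05, 0.001, 0.049),
                   sample_id = "s1", stringsAsFactors = FALSE)
  kept <- filter_significant(ev)
  expect_equal(kept$inc_diff, c(0.06, 0.2))
  expect_identical(filter_significant(kept), kept)
})

test_that("recurrence uses the ceiling rule and sign-aware keys", {
  mk <- function(sample, diff, coords = "10:20:30:40:50:60") {
    data.frame(event_type = "RI", gene = "G", chrom = "chr1",
               strand = "+", coords = coords, inc_level_control = 0.3,
               inc_level_treated = 0.3 + diff, inc_diff = diff,
               fdr = 0.01, sample_id = sample, stringsAsFactors = FALSE)
  }
  # present in 9 of 18 samples: ceil(0.5 * 18) = 9, kept
  by_sample <- c(lapply(1:9, function(i) mk(paste0("s", i), 0.2)),
                 lapply(10:18, function(i)
                   mk(paste0("s", i), 0.2, coords = paste0("1:2:3:4:5:", i))))
  names(by_sample) <- paste0("s", 1:18)
  rec <- find_recurrent(by_sample, 0.5)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$n_samples, 9)
  expect_equal(rec$mean_inc_diff, 0.2)

  # 5 of 12 samples: ceil(6) = 6, dropped
  by12 <- c(lapply(1:5, function(i) mk(paste0("s", i), 0.2)),
            lapply(6:12, function(i)
              mk(paste0("s", i), 0.2, coords = paste0("9:8:7:6:5:", i))))
  names(by12) <- paste0("s", 1:12)
  expect_equal(nrow(find_recurrent(by12, 0.5)), 0)

  # opposite signs at identical coordinates are distinct keys
  two <- list(s1 = mk("s1", 0.1), s2 = mk("s2", -0.1))
  expect_equal(nrow(find_recurrent(two, 0)), 2)
  expect_equal(nrow(find_recurrent(two, 1)), 0)
})

test_that("recurrence agrees with the brute-force matcher on random tables", {
  set.seed(601)
  for (rep in 1:10) {
    pool <- make_key_pool(30)
    n_samp <- sample(3:8, 1)
    evs <- lapply(seq_len(n_samp), function(s)
      random_splice_events(sample(20:120, 1), paste0("s", s), pool))
    names(evs) <- paste0("s", seq_len(n_samp))
    frac <- sample(c(0, 0.3, 0.5, 1), 1)
    mine <- find_recurrent(evs, frac)
    ref <- oracle_recurrent(evs, frac)
    expect_equal(nrow(mine), length(ref))
    if (length(ref)) {
      ref_keys <- sort(vapply(ref, function(x)
        paste(x$event_type, x$chrom, x$strand, x$coords, x$sign),
        character(1)))
      my_keys <- sort(paste(mine$event_type, mine$chrom, mine$strand,
                            mine$coords, mine$sign))
      expect_identical(my_keys, ref_keys)
    }
  }
})

test_that("global orientation flip negates signs but preserves structure", {
  set.seed(602)
  pool <- make_key_pool(15)
  evs <- lapply(1:4, function(s)
    random_splice_events(60, paste0("s", s), pool))
  names(evs) <- paste0("s", 1:4)
  flipped <- lapply(evs, function(e) { e$inc_diff <- -e$inc_diff; e })
  a <- find_recurrent(evs, 0.5)
  b <- find_recurrent(flipped, 0.5)
  expect_equal(nrow(a), nrow(b))
  a_sorted <- a[order(a$coords), ]; b_sorted <- b[order(b$coords), ]
  expect_equal(a_sorted$sign, -b_sorted$sign)
  expect_equal(a_sorted$mean_inc_diff, -b_sorted$mean_inc_diff)
})

test_that("type summary tallies events and RI directionality", {
  ev <- data.frame(event_type = c("SE", "SE", "SE", "RI", "RI", "RI"),
                   inc_diff = c(0.1, 0.2, -0.1, 0.3, 0.2, -0.4))
  ts <- type_summary(ev)
  expect_equal(ts$type_counts[["SE"]], 3)
  expect_equal(ts$type_counts[["RI"]], 3)
  expect_equal(ts$ri_direction$n_positive, 2)
  expect_equal(ts$ri_direction$n_negative, 1)
  expect_equal(ts$ri_direction$fraction_positive, 2 / 3)

  none <- type_summary(data.frame(event_type = character(),
                                  inc_diff = numeric()))
  expect_true(all(none$type_counts == 0))
  expect_true(is.na(none$ri_direction$fraction_positive))
})

test_that("generated splice tables round-trip and recover planted truth", {
  d <- tempfile()
  sim <- gen_splice_tables(603, d, n_samples = 12)
  evs <- lapply(sim$samples, function(s)
    filter_significant(read_rmats_tables(file.path(d, s), s)))
  names(evs) <- sim$samples
  rec <- find_recurrent(evs, 0.5)
  rec_keys <- paste(rec$event_type, rec$chrom, rec$strand, rec$coords,
                    ifelse(rec$sign > 0, "+1", "-1"), sep = "|")
  want <- sim$truth[sim$truth$n_samples_planted >= 6, ]
  expect_setequal(rec_keys, want$key)
  got_n <- rec$n_samples[match(want$key, rec_keys)]
  expect_equal(got_n, want$n_samples_planted)

  # determinism: regenerating with the same seed is byte-identical
  d2 <- tempfile()
  gen_splice_tables(603, d2, n_samples = 12)
  f1 <- list.files(d, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  sums1 <- unname(tools::md5sum(file.path(d, f1)))
  sums2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(sums1, sums2)
})
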