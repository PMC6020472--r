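test_that("Spearman rho handles monotone, reversed and tied data", {
  s <- spearman_rho(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(s$rho, 1)
  expect_equal(s$p_value, 0)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(8, 6, 4, 2))$rho, -1)
  # ties get average ranks: ranks of (1,2,2,4) are (1, 2.5, 2.5, 4)
  expect_equal(rank(c(1, 2, 2, 4), ties.method = "average"),
               c(1, 2.5, 2.5, 4))
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:3, 1:3), "at least 4")
})

test_that("rho equals Pearson on explicit average ranks (tied data)", {
  set.seed(901)
  for (i in 1:300) {
    n <- sample(5:20, 1)
    x <- sample(1:6, n, replace = TRUE) + rnorm(n, 0, 1e-9)
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    mine <- spearman_rho(x, y)
    ref <- cor(rank(x, ties.method = "average"),
               rank(y, ties.method = "average"))
    expect_equal(mine$rho, ref, tolerance = 1e-10)
  }
})

test_that("exact permutation p-value is a valid two-sided tail", {
  set.seed(902)
  x <- c(0.3, 1.2, 0.7, 2.0, 1.5)
  y <- c(0.1, 1.0, 0.9, 1.7, 1.2)
  ex <- spearman_rho(x, y, exact = TRUE)
  # enumeration over all 120 permutations, done independently here
  perms <- matrix(unlist(combinat_perms <- local({
    rec <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (rest in rec(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
      out
    }
    rec(seq_along(y))
  })), ncol = length(y), byrow = TRUE)
  rhos <- apply(perms, 1, function(p)
    cor(rank(x), rank(y[p])))
  expect_equal(ex$p_value,
               mean(abs(rhos) >= abs(ex$rho) - 1e-12),
               tolerance = 1e-12)
  expect_error(spearman_rho(rnorm(9), rnorm(9), exact = TRUE), "n <= 8")
})

test_that("correlated pairs keeps only planted co-expression", {
  set.seed(903)
  n_samp <- 12
  genes <- c(paste0("S", 1:6), paste0("M", 1:6))
  vals <- matrix(rnorm(length(genes) * n_samp), length(genes), n_samp,
                 dimnames = list(genes, paste0("x", 1:n_samp)))
  latent <- rnorm(n_samp)
  vals["S1", ] <- latent + rnorm(n_samp, 0, 0.05)
  vals["M1", ] <- latent + rnorm(n_samp, 0, 0.05)
  ds <- expression_dataset("d", vals,
                           setNames(rep(c("control", "treated"),
                                        6), colnames(vals)))
  pairs <- correlated_pairs(ds, paste0("S", 1:6), paste0("M", 1:6))
  expect_equal(nrow(pairs), 1)
  expect_identical(pairs$gene_a, "S1")
  expect_identical(pairs$gene_b, "M1")
  expect_gt(pairs$rho, 0.7)

  # strict rho threshold: raising rho_min just above the attained rho drops it
  none <- correlated_pairs(ds, paste0("S", 1:6), paste0("M", 1:6),
                           rho_min = pairs$rho)
  expect_equal(nrow(none), 0)
  expect_error(correlated_pairs(ds, "absent", paste0("M", 1:6)),
               "splicing-set")
})

test_that("pair correlation is symmetric in the two gene sets", {
  set.seed(904)
  vals <- matrix(rnorm(6 * 10), 6, 10,
                 dimnames = list(c("A1", "A2", "B1", "B2", "C1", "C2"),
                                 paste0("x", 1:10)))
  ds <- expression_dataset("d", vals,
                           setNames(rep(c("control", "treated"), 5),
                                    colnames(vals)))
  ab <- correlated_pairs(ds, c("A1", "A2"), c("B1", "B2"),
                         rho_min = -1.1, alpha = 1.1)
  ba <- correlated_pairs(ds, c("B1", "B2"), c("A1", "A2"),
                         rho_min = -1.1, alpha = 1.1)
  key_ab <- paste(ab$gene_a, ab$gene_b)
  key_ba <- paste(ba$gene_b, ba$gene_a)
  expect_equal(ab$rho[order(key_ab)], ba$rho[order(key_ba)],
               tolerance = 1e-12)
})

test_that("promoter-window binding respects half-open interval arithmetic", {
  tss <- data.frame(gene = "G1", chrom = "chr1", strand = "+",
                    tss = 3000)
  hit <- data.frame(chrom = "chr1", start = 995, end = 1005, tf = "TF1")
  map <- build_tf_map(hit, tss, window = 2000)
  expect_identical(map$targets$TF1, "G1")

  miss <- data.frame(chrom = "chr1", start = 0, end = 999, tf = "TF1")
  map2 <- build_tf_map(miss, tss, window = 2000)
  expect_null(map2$targets$TF1)

  # exactly touching the window start base is a 1-bp overlap
  touch <- data.frame(chrom = "chr1", start = 999, end = 1001, tf = "TF1")
  expect_identical(build_tf_map(touch, tss, 2000)$targets$TF1, "G1")

  other_chrom <- data.frame(chrom = "chr2", start = 2900, end = 3100,
                            tf = "TF1")
  expect_null(suppressWarnings(
    build_tf_map(other_chrom, tss, 2000))$targets$TF1)

  expect_error(build_tf_map(data.frame(chrom = "chr1", start = 10,
                                       end = 10, tf = "T"), tss),
               "end <= start")
})

test_that("common TFs are the intersection over datasets", {
  tf_map <- structure(list(targets = list(TFA = c("a", "b"),
                                          TFB = c("a", "b"),
                                          TFC = c("x", "y")),
                           window = 2000), class = "TFBindingMap")
  pair <- data.frame(gene_a = "a", gene_b = "b", rho = 0.9,
                     p_value = 0.001, q_value = 0.01,
                     stringsAsFactors = FALSE)
  other <- data.frame(gene_a = "x", gene_b = "y", rho = 0.9,
                      p_value = 0.001, q_value = 0.01,
                      stringsAsFactors = FALSE)
  res <- common_tfs(list(d1 = pair, d2 = pair, d3 = pair,
                         d4 = pair), tf_map)
  expect_setequal(res$common_tfs, c("TFA", "TFB"))
  expect_true(all(res$edges$tf %in% c("TFA", "TFB")))

  # TFA/TFB qualify in only 3 of 4 datasets, TFC in only 1: none common
  res2 <- suppressMessages(common_tfs(list(d1 = pair, d2 = pair,
                                           d3 = pair, d4 = other),
                                      tf_map))
  expect_length(res2$common_tfs, 0)
  # adding a dataset can only shrink the common set
  expect_true(all(res2$common_tfs %in% res$common_tfs))

  solo <- data.frame(gene_a = "q", gene_b = "r", rho = 0.9,
                     p_value = 0.001, q_value = 0.01,
                     stringsAsFactors = FALSE)
  expect_message(res3 <- common_tfs(list(d1 = solo), tf_map),
                 "no transcription factor")
  expect_length(res3$common_tfs, 0)
})

test_that("the planted TF fixture is recovered end to end", {
  fix <- gen_tf_fixture(905)
  pairs <- lapply(fix$datasets, function(ds)
    correlated_pairs(ds, fix$splicing_genes, fix$mitotic_genes))
  tf_map <- build_tf_map(fix$peaks, fix$tss, window = 2000)
  res <- common_tfs(pairs, tf_map)
  expect_identical(res$common_tfs, fix$truth$common_tfs)
  expect_false(fix$truth$partial_tfs %in% res$common_tfs)
  # the partial TF does qualify in the datasets it was planted in
  expect_true(fix$truth$partial_tfs %in% res$per_dataset[[1]])
})

test_that("peak and TSS readers validate their inputs", {
  f <- tempfile()
  writeLines(c("chr1\t10\t20\tTF1", "chr2\t5\t9\tTF2"), f)
  peaks <- read_bed_peaks(f)
  expect_equal(nrow(peaks), 2)
  expect_identical(names(peaks), c("chrom", "start", "end", "tf"))

  g <- tempfile()
  writeLines(c("gene\tchrom\tstrand\ttss", "G1\tchr1\t+\t100",
               "G1\tchr1\t+\t200"), g)
  expect_error(read_tss_table(g), "one TSS per gene")
})
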