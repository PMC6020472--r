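sep_profiles <- function(n_per = 30, noise = 0.1, seed = 801) {
  set.seed(seed)
  t1 <- c(-1, -0.3, 0.3, 1); t2 <- -t1
  x <- rbind(matrix(rep(t1, each = n_per), n_per) +
               rnorm(n_per * 4, 0, noise),
             matrix(rep(t2, each = n_per), n_per) +
               rnorm(n_per * 4, 0, noise))
  rownames(x) <- paste0("g", seq_len(2 * n_per))
  list(x = x, labels = rep(1:2, each = n_per))
}

test_that("memberships are a partition and the objective never increases", {
  sp <- sep_profiles()
  fit <- fuzzy_cmeans(sp$x, c = 2, m = 2, seed = 1)
  expect_lt(max(abs(rowSums(fit$membership) - 1)), 1e-9)
  expect_true(all(diff(fit$objective_trace) <= 1e-9))
  expect_true(all(fit$membership >= 0 & fit$membership <= 1))
})

test_that("well-separated groups get confident memberships", {
  sp <- sep_profiles(noise = 0.1)
  fit <- fuzzy_cmeans(sp$x, c = 2, m = 2, seed = 2)
  top <- apply(fit$membership, 1, max)
  expect_true(all(top >= 0.9))
  hard <- cluster_gene_assignment(fit, 0.5)
  expect_equal(length(unique(hard[1:30])), 1)
  expect_equal(length(unique(hard[31:60])), 1)
  expect_false(hard[1] == hard[31])
})

test_that("a gene identical to a converged center takes full membership", {
  # two exactly repeated profiles: centers converge onto them
  x <- rbind(matrix(rep(c(1, 0, -1, 0), each = 10), 10),
             matrix(rep(c(-1, 0, 1, 0), each = 10), 10))
  rownames(x) <- paste0("g", 1:20)
  fit <- fuzzy_cmeans(x, c = 2, m = 2, seed = 3)
  expect_true(all(apply(fit$membership, 1, max) > 1 - 1e-9))
})

test_that("an equidistant gene splits its membership evenly at m = 2", {
  x <- rbind(matrix(rep(c(1, 1, 1, 1), each = 15), 15) +
               matrix(rnorm(60, 0, 0.01), 15),
             matrix(rep(c(-1, -1, -1, -1), each = 15), 15) +
               matrix(rnorm(60, 0, 0.01), 15),
             mid = c(0, 0, 0, 0))
  rownames(x) <- paste0("g", 1:31)
  fit <- fuzzy_cmeans(x, c = 2, m = 2, seed = 4)
  expect_equal(unname(fit$membership[31, ]), c(0.5, 0.5),
               tolerance = 0.01)
})

test_that("hard assignment respects the membership threshold", {
  fake <- structure(list(c = 2, m = 2,
                         membership = rbind(a = c(0.7, 0.3),
                                            b = c(0.45, 0.55)),
                         centers = rbind(c(1, 0), c(0, 1))),
                    class = "FuzzyClustering")
  expect_equal(unname(cluster_gene_assignment(fake, 0.5)), c(1L, 2L))
  expect_equal(unname(cluster_gene_assignment(fake, 0.6)),
               c(1L, NA_integer_))
  expect_false(anyNA(cluster_gene_assignment(fake, 0)))
  expect_error(cluster_gene_assignment(fake, 1.2), "min_membership")
})

test_that("trend labels reflect strict monotonicity of the center", {
  fake <- structure(list(c = 3, m = 2,
                         centers = rbind(c(1, 0.5, 0, -1),
                                         c(0, 0, 0, 0),
                                         c(-1, 0, 0.5, 1)),
                         membership = matrix(1 / 3, 5, 3)),
                    class = "FuzzyClustering")
  expect_identical(cluster_trend(fake, 1)$label, "decreasing")
  expect_identical(cluster_trend(fake, 2)$label, "non-monotone")
  expect_identical(cluster_trend(fake, 3)$label, "increasing")
  expect_error(cluster_trend(fake, 4), "cluster index")
})

test_that("a planted decreasing cluster is labeled decreasing", {
  hits <- 0L
  for (seed in 1:20) {
    tc <- gen_timecourse(seed)
    fit <- fuzzy_cmeans(tc$data, c = 3, m = 2, seed = seed)
    labels <- vapply(1:3, function(j) cluster_trend(fit, j)$label,
                     character(1))
    # the planted decreasing template must surface as a decreasing center
    truth_dec <- names(which(tc$labels == 1))
    hard <- cluster_gene_assignment(fit, 0)
    main <- as.integer(names(sort(table(hard[truth_dec]),
                                  decreasing = TRUE))[1])
    if (labels[main] == "decreasing") hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("row permutation only relabels clusters", {
  sp <- sep_profiles(noise = 0.15, seed = 802)
  fit1 <- fuzzy_cmeans(sp$x, c = 2, m = 2, seed = 5)
  perm <- sample(nrow(sp$x))
  fit2 <- fuzzy_cmeans(sp$x[perm, ], c = 2, m = 2, seed = 5)
  d <- as.matrix(dist(rbind(fit1$centers, fit2$centers)))[1:2, 3:4]
  matching <- apply(d, 1, which.min)
  expect_setequal(matching, 1:2)
  expect_lt(max(apply(d, 1, min)), 0.05)
})

test_that("degenerate cluster requests are rejected", {
  x <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("g", 1:5), NULL))
  expect_error(fuzzy_cmeans(x, c = 5), "smaller than")
  expect_error(fuzzy_cmeans(x, c = 1), "at least 2")
  expect_error(fuzzy_cmeans(x, c = 2, m = 1), "> 1")
})

test_that("centers agree with an independent fuzzy c-means implementation", {
  sp <- sep_profiles(noise = 0.2, seed = 803)
  fit <- fuzzy_cmeans(sp$x, c = 2, m = 2, seed = 6)
  ref <- e1071::cmeans(sp$x, centers = 2, m = 2, iter.max = 500)
  d <- as.matrix(dist(rbind(fit$centers, ref$centers)))[1:2, 3:4]
  expect_lt(max(apply(d, 1, min)), 0.02)
})

test_that("the cluster-count sweep finds the planted structure", {
  tc <- gen_timecourse(804, sizes = 60)
  sel <- select_cluster_number(tc$data, c_range = 2:6, seed = 7)
  expect_equal(nrow(sel$table), 5)
  expect_true(sel$suggested_c %in% 2:6)
})

test_that("timeseries_matrix averages replicates and enforces timepoints", {
  vals <- matrix(rnorm(40), 5, 8,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  groups <- setNames(rep("treated", 8), colnames(vals))
  times <- setNames(rep(c(0, 6, 12, 24), each = 2), colnames(vals))
  ds <- expression_dataset("tc", vals, groups, time_of = times)
  tm <- timeseries_matrix(ds)
  expect_equal(tm$timepoints, c(0, 6, 12, 24))
  expect_equal(dim(tm$values), c(5, 4))
  expect_lt(max(abs(rowMeans(tm$values))), 1e-9)

  short <- expression_dataset("tc", vals[, 1:4],
                              groups[1:4], time_of = times[1:4])
  expect_error(timeseries_matrix(short), "4 distinct timepoints")
})
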