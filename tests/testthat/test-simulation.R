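test_that("identical seeds give bit-identical simulations", {
  a <- simulate_batches(n_genes = 100, n_per_batch = 50, seed = 123)
  b <- simulate_batches(n_genes = 100, n_per_batch = 50, seed = 123)
  expect_identical(a, b)
  c <- simulate_batches(n_genes = 100, n_per_batch = 50, seed = 124)
  expect_false(identical(a$batches, c$batches))
})

test_that("simulation invariants: reference shift zero, disjoint markers", {
  sim <- simulate_batches(n_genes = 200, n_types = 4, n_queries = 2,
                          n_per_batch = 60, seed = 9)
  expect_true(all(sim$truth$batch_shifts[, 1] == 0))
  mk <- sim$truth$marker_genes_of_type
  expect_equal(length(unlist(mk)), length(unique(unlist(mk))))
  expect_length(sim$batches, 3)
  expect_true(all(sim$batches$batch0$values >= 0))
  # shared panel, shared order
  expect_identical(gene_ids(sim$batches$batch0), gene_ids(sim$batches$batch2))
})

test_that("within-type within-batch gene means match the planted model", {
  sim <- simulate_batches(n_genes = 150, n_types = 2, n_queries = 1,
                          n_per_batch = 400, markers_per_type = 10,
                          batch_effect_sd = 0.5, noise_sd = 0.4, seed = 31)
  for (b in names(sim$batches)) {
    x <- sim$batches[[b]]
    for (type in colnames(sim$truth$type_means)) {
      cells <- names(sim$truth$cell_type_of)[
        sim$truth$cell_type_of == type &
          sim$truth$batch_of == b]
      n <- length(cells)
      expected <- sim$truth$type_means[, type] + sim$truth$batch_shifts[, b]
      got <- rowMeans(x$values[, cells])
      # clamping at zero only lifts means; allow 4 sd/sqrt(n) plus the
      # (small) clamp bias on genes whose expected value is far from 0
      ok <- expected > 4 * 0.4
      expect_true(all(abs(got - expected)[ok] < 4 * 0.4 / sqrt(n) + 0.02))
    }
  }
})

test_that("null signal means marker recovery at chance", {
  sim <- simulate_batches(n_genes = 300, n_types = 2, n_queries = 0,
                          n_per_batch = 100, markers_per_type = 10,
                          marker_effect = 0, batch_effect_sd = 0, seed = 77)
  x <- sim$batches[[1]]
  truth_type <- sim$truth$cell_type_of[cell_ids(x)]
  labels <- setNames(as.integer(factor(truth_type)), cell_ids(x))
  assign <- structure(list(batch_id = x$batch_id, labels = labels,
                           centroids = NULL, K = 2L,
                           sizes = tabulate(labels, 2),
                           small = c(FALSE, FALSE), seed = 0L),
                      class = "cluster_assignment")
  ms <- marker_genes(x, assign, 1, h = 10)
  hits <- length(intersect(ms$genes, sim$truth$marker_genes_of_type$type1))
  expect_lte(hits, 4)  # 10 planted among 300 genes: chance is ~0.3 hits
})

test_that("batch-private types via zero proportions", {
  sim <- simulate_batches(n_genes = 120, n_types = 3, n_queries = 1,
                          n_per_batch = 90,
                          type_proportions = list(c(0.5, 0.5, 0),
                                                  c(0.4, 0.3, 0.3)),
                          markers_per_type = 8, seed = 15)
  t0 <- sim$truth$cell_type_of[sim$truth$batch_of == "batch0"]
  t1 <- sim$truth$cell_type_of[sim$truth$batch_of == "batch1"]
  expect_false("type3" %in% t0)
  expect_true("type3" %in% t1)
  expect_equal(length(t0), 90)
  expect_equal(length(t1), 90)
})

test_that("the two-batch private-type scenario has the stated structure", {
  sim <- dataset3_scenario(seed = 5)
  expect_equal(ncol(sim$batches$batch0$values), 288)  # 3 x 96 cells
  expect_equal(ncol(sim$batches$batch1$values), 288)
  tab0 <- table(sim$truth$cell_type_of[sim$truth$batch_of == "batch0"])
  tab1 <- table(sim$truth$cell_type_of[sim$truth$batch_of == "batch1"])
  expect_equal(unname(tab0[c("type1", "type2", "private1")]), rep(96L, 3),
               ignore_attr = TRUE)
  expect_equal(unname(tab1[c("type1", "type2", "private2")]), rep(96L, 3),
               ignore_attr = TRUE)
  expect_false("private2" %in% names(tab0))
  expect_false("private1" %in% names(tab1))
  # the private types are similar: marker sets overlap
  mk <- sim$truth$marker_genes_of_type
  expect_gt(length(intersect(mk$private1, mk$private2)), 0)
  # shared-type cells differ across batches only by shift + noise: the
  # cross-batch mean difference for type1 tracks the planted batch shift
  c0 <- names(sim$truth$cell_type_of)[sim$truth$cell_type_of == "type1" &
                                        sim$truth$batch_of == "batch0"]
  c1 <- names(sim$truth$cell_type_of)[sim$truth$cell_type_of == "type1" &
                                        sim$truth$batch_of == "batch1"]
  dmean <- rowMeans(sim$batches$batch1$values[, c1]) -
    rowMeans(sim$batches$batch0$values[, c0])
  shift <- sim$truth$batch_shifts[, "batch1"]
  ok <- (sim$truth$type_means[, "type1"] + pmin(shift, 0)) > 2  # clamp-free genes
  expect_lt(max(abs((dmean - shift)[ok])), 4 * 0.5 * sqrt(2 / 96) + 0.02)
})

test_that("simulation input validation", {
  expect_error(simulate_batches(n_types = 1), "at least two")
  expect_error(simulate_batches(n_genes = 20, n_types = 4,
                                markers_per_type = 10), "too small")
  expect_error(simulate_batches(type_proportions = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
  expect_error(simulate_batches(n_per_batch = c(10, 10, 10)),
               "one entry per batch")
})
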