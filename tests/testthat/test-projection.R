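random_centroids <- function(p, m, seed) {
  set.seed(seed)
  matrix(rnorm(p * m) + 2, p, m)
}

test_that("centroid pair matrices follow the putative pairs, in order", {
  sim <- simulate_batches(n_genes = 60, n_types = 3, n_per_batch = 60,
                          markers_per_type = 6, seed = 17)
  ref <- cluster_batch(sim$batches$batch0, 5, seed = 1)
  qry <- cluster_batch(sim$batches$batch1, 5, seed = 1)
  pairs <- data.frame(query_batch = "batch1", query_cluster = c(2L, 4L, 1L),
                      ref_cluster = c(3L, 3L, 1L), overlap = c(5L, 4L, 3L),
                      p_value = c(1e-6, 1e-4, 1e-2), putative = TRUE)
  cm <- centroid_pair_matrices(qry, ref, pairs)
  expect_equal(ncol(cm$Xc_query), 3)
  # columns equal means recomputed by brute force from labels
  for (j in 1:3) {
    qk <- pairs$query_cluster[j]
    expect_equal(unname(cm$Xc_query[, j]),
                 unname(rowMeans(sim$batches$batch1$values[, qry$labels == qk])))
    rk <- pairs$ref_cluster[j]
    expect_equal(unname(cm$Xc_ref[, j]),
                 unname(rowMeans(sim$batches$batch0$values[, ref$labels == rk])))
  }
  # duplicated reference match contributes its centroid twice
  expect_equal(cm$Xc_ref[, 1], cm$Xc_ref[, 2], ignore_attr = TRUE)
  # permuting pair order permutes columns identically
  cm2 <- centroid_pair_matrices(qry, ref, pairs[c(3, 1, 2), ])
  expect_equal(unname(cm2$Xc_query), unname(cm$Xc_query[, c(3, 1, 2)]))
  expect_equal(unname(cm2$Xc_ref), unname(cm$Xc_ref[, c(3, 1, 2)]))
  # zero putative pairs reject with advice
  pairs$putative <- FALSE
  expect_error(centroid_pair_matrices(qry, ref, pairs), "raising omega")
})

test_that("a cell at a matched query centroid maps to the reference centroid", {
  p <- 25; m <- 4
  Xq <- random_centroids(p, m, 31)
  Xr <- random_centroids(p, m, 32)
  x <- expression_matrix(abs(Xq[, 2, drop = FALSE]),
                         gene_ids = sprintf("g%d", 1:p), cell_ids = "cell1",
                         batch_id = "q")
  got <- project_batch(x, abs(Xq), Xr)
  expect_equal(unname(got$values[, 1]), unname(Xr[, 2]), tolerance = 1e-8)
})

test_that("projection onto an orthonormal own-span basis is the identity", {
  p <- 30; m <- 5
  Q <- qr.Q(qr(random_centroids(p, m, 33)))  # orthonormal columns
  set.seed(34)
  coef <- matrix(rnorm(m * 7), m, 7)
  X <- Q %*% coef
  x <- structure(list(values = `dimnames<-`(X, list(sprintf("g%d", 1:p),
                                                    sprintf("c%d", 1:7))),
                      batch_id = "q"), class = "expr_mat")
  got <- project_batch(x, Q, Q)
  expect_equal(unname(got$values), unname(X), tolerance = 1e-8)
})

test_that("projection matches the per-cell normal-equation oracle", {
  set.seed(40)
  for (i in 1:20) {
    p <- sample(10:50, 1); m <- sample(2:8, 1); n <- sample(3:30, 1)
    Xq <- matrix(rnorm(p * m) + 2, p, m)
    Xr <- matrix(rnorm(p * m) + 2, p, m)
    X <- matrix(abs(rnorm(p * n)), p, n,
                dimnames = list(sprintf("g%d", 1:p), sprintf("c%d", 1:n)))
    x <- structure(list(values = X, batch_id = "q"), class = "expr_mat")
    got <- project_batch(x, Xq, Xr)$values
    want <- oracle_project(X, Xq, Xr)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-8)
  }
})

test_that("the projection map is linear (interpolation property)", {
  p <- 40; m <- 5
  Xq <- random_centroids(p, m, 50)
  Xr <- random_centroids(p, m, 51)
  set.seed(52)
  xa <- abs(rnorm(p)); xb <- abs(rnorm(p))
  proj1 <- function(v) {
    x <- structure(list(values = matrix(v, p, 1,
                                        dimnames = list(sprintf("g%d", 1:p), "c")),
                        batch_id = "q"), class = "expr_mat")
    project_batch(x, Xq, Xr)$values[, 1]
  }
  pa <- proj1(xa); pb <- proj1(xb)
  for (alpha in c(0, 0.25, 0.5, 0.9, 1)) {
    expect_equal(proj1(alpha * xa + (1 - alpha) * xb),
                 alpha * pa + (1 - alpha) * pb, tolerance = 1e-8)
  }
})

test_that("midpoints of matched query centroids map to reference midpoints", {
  p <- 35; m <- 6
  Xq <- random_centroids(p, m, 60)
  Xr <- random_centroids(p, m, 61)
  mid <- (Xq[, 1] + Xq[, 4]) / 2
  x <- structure(list(values = matrix(mid, p, 1,
                                      dimnames = list(sprintf("g%d", 1:p), "c")),
                      batch_id = "q"), class = "expr_mat")
  got <- project_batch(x, Xq, Xr)$values[, 1]
  expect_equal(unname(got), unname((Xr[, 1] + Xr[, 4]) / 2), tolerance = 1e-8)
})

test_that("rank-deficient centroid matrices get the minimum-norm solution", {
  p <- 20
  base <- random_centroids(p, 2, 70)
  Xq <- cbind(base, base[, 1])          # duplicated column: rank 2
  Xr <- random_centroids(p, 3, 71)
  set.seed(72)
  X <- matrix(abs(rnorm(p * 4)), p, 4,
              dimnames = list(sprintf("g%d", 1:p), sprintf("c%d", 1:4)))
  x <- structure(list(values = X, batch_id = "q"), class = "expr_mat")
  got <- project_batch(x, Xq, Xr)
  beta <- attr(got, "beta")
  # beta solves the (singular) normal equations
  expect_lt(max(abs(t(Xq) %*% (X - Xq %*% beta))), 1e-8 * max(abs(X)))
  # minimum-norm: beta lies in the row space of Xq
  ns <- c(1, 0, -1) / sqrt(2)  # null-space direction of Xq's columns
  expect_lt(max(abs(t(ns) %*% beta)), 1e-8)
})

test_that("projection input validation", {
  p <- 10
  Xq <- random_centroids(p, 2, 80)
  x <- random_expr(p, 3, seed = 81)
  expect_error(project_batch(x, Xq[1:5, ], Xq), "one row per gene")
  expect_error(project_batch(x, Xq, Xq[, 1, drop = FALSE]), "same number")
  expect_error(project_batch(x, matrix(0, p, 2), Xq), "all zero")
  # clamping produces no negative values
  Xr <- -random_centroids(p, 2, 82)
  got <- project_batch(x, Xq, Xr, clamp_nonnegative = TRUE)
  expect_true(all(got$values >= 0))
})
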