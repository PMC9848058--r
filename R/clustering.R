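#' Default number of clusters for over-clustering a batch
#'
#' The pipeline deliberately over-clusters: the cluster count should be well
#' above the number of cell types, so that large types break into several
#' homogeneous groups (giving a high-resolution centroid basis for the
#' projection step) while outliers isolate into clusters of their own that
#' the matching step can discard. The default grows with the square root of
#' the reference batch size; the multiplier exposes the sensitivity grid
#' around it.
#'
#' @param n0 number of cells in the reference batch (must be >= 4).
#' @param multiplier positive scaling of the square-root rule (default 1).
#' @return `max(2, round(multiplier * sqrt(n0)))`.
#' @export
#' @examples
#' default_k(576)        # 24
#' default_k(100, 0.8)   # 8
default_k <- function(n0, multiplier = 1) {
  if (!is.numeric(n0) || length(n0) != 1L || n0 < 4)
    stop("n0 must be a single integer >= 4 (too few reference cells to cluster)")
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier <= 0)
    stop("multiplier must be a single positive number")
  max(2L, as.integer(round(multiplier * sqrt(n0))))
}

#' K-means clustering of one batch
#'
#' Clusters the cells of a single batch on their full expression profiles.
#' Clustering is always strictly per batch: pooling batches before
#' clustering would let batch effects drive the partition. Results are
#' deterministic for a fixed input (cell order) and seed. Empty clusters
#' after convergence are dropped and the realised `K` reported; clusters
#' with fewer than 3 cells are kept but flagged (the marker step decides
#' their fate).
#'
#' @param x an [expression_matrix()].
#' @param K number of clusters, `2 <= K <=` number of cells.
#' @param seed integer seed for the k-means restarts.
#' @param nstart,iter.max passed to [stats::kmeans()].
#' @return An object of class `cluster_assignment`: list with `batch_id`,
#'   `labels` (named integer vector in `1..K`), `centroids` (gene x K
#'   matrix, column k the mean of cluster k's cells), `K`, `sizes`,
#'   `small` (logical flag per cluster for size < 3) and `seed`.
#' @export
cluster_batch <- function(x, K, seed = 0L, nstart = 10L, iter.max = 300L) {
  stopifnot(inherits(x, "expr_mat"))
  n <- ncol(x$values)
  if (!all(is.finite(x$values))) stop("non-finite expression values")
  if (!is.numeric(K) || length(K) != 1L || K < 2) stop("K must be >= 2")
  if (K > n) stop("K (", K, ") exceeds the number of cells (", n, ")")
  K <- as.integer(K)

  set.seed(as.integer(seed))
  km <- suppressWarnings(
    stats::kmeans(t(x$values), centers = K, nstart = nstart,
                  iter.max = iter.max)
  )
  labels <- as.integer(km$cluster)

  # drop empty clusters (rare) and renumber 1..K'
  occupied <- sort(unique(labels))
  labels <- match(labels, occupied)
  Kr <- length(occupied)

  centroids <- vapply(seq_len(Kr), function(k)
    rowMeans(x$values[, labels == k, drop = FALSE]),
    numeric(nrow(x$values)))
  dimnames(centroids) <- list(gene_ids(x), as.character(seq_len(Kr)))
  sizes <- tabulate(labels, Kr)
  names(labels) <- cell_ids(x)

  structure(list(batch_id = x$batch_id, labels = labels,
                 centroids = centroids, K = Kr, sizes = sizes,
                 small = sizes < 3L, seed = as.integer(seed)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> batch '%s': %d cells in %d clusters (sizes %s)\n",
              x$batch_id, length(x$labels), x$K,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Write cluster labels to a TSV file
#'
#' @param assignment a `cluster_assignment`.
#' @param path output TSV path (columns cell_id, batch, cluster).
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(assignment, path) {
  df <- data.frame(cell_id = names(assignment$labels),
                   batch = assignment$batch_id,
                   cluster = unname(assignment$labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
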