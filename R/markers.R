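#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) two-sample t statistic with
#' Welch--Satterthwaite degrees of freedom and a two-sided p-value. Used
#' per gene to compare a cluster against all other cells of its batch.
#' Degenerate inputs are handled explicitly: if both groups have zero
#' variance the test returns `t = 0, p = 1` when the means agree and
#' `t = +/-Inf, p = 0` when they differ.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return List with elements `t` and `p`.
#' @export
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6, 7))
two_sample_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values for a two-sample t-test")
  res <- welch_rows(matrix(group_a, nrow = 1L), matrix(group_b, nrow = 1L))
  list(t = unname(res$t), p = unname(res$p))
}

# Vectorised Welch test over the rows of two matrices (same row count).
# Returns t, p and the mean difference a - b per row.
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- row_vars(a); vb <- row_vars(b)
  se2 <- va / na + vb / nb
  d <- ma - mb
  t <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, sign(d) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               1)
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df),
              ifelse(t == 0, 1, 0))
  p[!is.finite(t) & t == 0] <- 1  # guard, unreachable by construction
  list(t = t, p = p, diff = d)
}

#' Marker genes of one cluster
#'
#' For a single cluster, tests every gene with a Welch t-test of the
#' cluster's cells against all other cells of the same batch, keeps genes
#' up-regulated in the cluster (positive mean difference) and returns the
#' `h` with the smallest two-sided p-values. Ties in p are broken by larger
#' mean difference, then by gene panel order, so the ranking is
#' deterministic. If the cluster or its complement has fewer than 3 cells
#' the cluster is untestable and an empty, flagged marker set is returned;
#' such clusters can never enter a matched pair.
#'
#' @param x the batch's [expression_matrix()].
#' @param assignment the batch's [cluster_batch()] result.
#' @param cluster_id cluster to test (integer in `1..K`).
#' @param h maximum number of markers to return (default 75).
#' @return An object of class `marker_set`: list with `batch_id`,
#'   `cluster_id`, `genes` (<= h ids, p ascending), `p_values`, `h`,
#'   `testable`.
#' @export
marker_genes <- function(x, assignment, cluster_id, h = 75) {
  stopifnot(inherits(x, "expr_mat"), inherits(assignment, "cluster_assignment"))
  if (!identical(x$batch_id, assignment$batch_id))
    stop("markers are computed strictly within one batch; batch ids differ")
  if (!is.numeric(h) || length(h) != 1L || h < 1) stop("h must be >= 1")
  if (h > nrow(x$values)) stop("h exceeds the gene panel size")
  if (!cluster_id %in% seq_len(assignment$K)) stop("unknown cluster_id")

  inside <- assignment$labels == cluster_id
  if (sum(inside) < 3L || sum(!inside) < 3L) {
    return(structure(list(batch_id = x$batch_id, cluster_id = cluster_id,
                          genes = character(0), p_values = numeric(0),
                          h = as.integer(h), testable = FALSE),
                     class = "marker_set"))
  }
  res <- welch_rows(x$values[, inside, drop = FALSE],
                    x$values[, !inside, drop = FALSE])
  up <- which(res$diff > 0)
  ord <- up[order(res$p[up], -res$diff[up], up)]
  take <- utils::head(ord, as.integer(h))
  structure(list(batch_id = x$batch_id, cluster_id = cluster_id,
                 genes = gene_ids(x)[take], p_values = unname(res$p[take]),
                 h = as.integer(h), testable = TRUE),
            class = "marker_set")
}

#' Marker sets for every cluster of a batch
#'
#' @inheritParams marker_genes
#' @return List of [marker_genes()] results, one per cluster `1..K`.
#' @export
all_marker_sets <- function(x, assignment, h = 75) {
  lapply(seq_len(assignment$K), function(k)
    marker_genes(x, assignment, k, h = h))
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> batch '%s' cluster %d: %d markers%s\n",
              x$batch_id, x$cluster_id, length(x$genes),
              if (x$testable) "" else " (untestable)"))
  invisible(x)
}
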