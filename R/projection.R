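#' Paired centroid matrices for the projection step
#'
#' Collects, in pair order, the centroids of the query clusters that have a
#' putative match (columns of `Xc_query`) and the centroids of their
#' matched reference clusters (`Xc_ref`, same column order). A reference
#' cluster matched by several query clusters contributes its centroid once
#' per pair, so the two matrices always have identical column counts.
#'
#' @param query_assign,ref_assign [cluster_batch()] results for the query
#'   and reference batches.
#' @param pairs data frame from [putative_matches()]; only rows with
#'   `putative == TRUE` are used.
#' @return List with `Xc_query`, `Xc_ref` (gene x m matrices) and `pairs`
#'   (the putative rows, in column order).
#' @export
centroid_pair_matrices <- function(query_assign, ref_assign, pairs) {
  stopifnot(inherits(query_assign, "cluster_assignment"),
            inherits(ref_assign, "cluster_assignment"))
  put <- pairs[which(pairs$putative %in% TRUE), , drop = FALSE]
  if (!nrow(put))
    stop("no putative matches; consider raising omega")
  if (any(!put$query_cluster %in% seq_len(query_assign$K)) ||
      any(!put$ref_cluster %in% seq_len(ref_assign$K)))
    stop("matched pair refers to an unknown cluster")
  Xc_query <- query_assign$centroids[, put$query_cluster, drop = FALSE]
  Xc_ref <- ref_assign$centroids[, put$ref_cluster, drop = FALSE]
  colnames(Xc_query) <- paste0("q", put$query_cluster)
  colnames(Xc_ref) <- paste0("r", put$ref_cluster)
  list(Xc_query = Xc_query, Xc_ref = Xc_ref, pairs = put)
}

#' Project a query batch onto the reference centroid space
#'
#' Every cell of the query batch — whether or not its own cluster has a
#' putative match — is decomposed as a least-squares linear combination of
#' the putatively matched query centroids, and re-synthesised from the
#' corresponding reference centroids:
#' \deqn{\hat\beta = (X_c^{q\top} X_c^q)^{-1} X_c^{q\top} X^q, \qquad
#'       \tilde X = X_c^{ref} \hat\beta.}
#' The map is linear, so cells between matched populations are interpolated
#' and outliers extrapolated rather than forced onto a matched centroid.
#' When the query centroid matrix is rank deficient (near-collinear
#' centroids), the minimum-norm least-squares solution is used via a
#' singular value decomposition instead of the explicit inverse.
#'
#' @param x_query the query [expression_matrix()].
#' @param Xc_query,Xc_ref gene x m centroid matrices from
#'   [centroid_pair_matrices()].
#' @param clamp_nonnegative if `TRUE`, clamp corrected values at 0 (the
#'   linear combination may undershoot). Default `FALSE`, preserving the
#'   formula exactly.
#' @return A `corrected_mat` (also an `expr_mat` structure, but corrected
#'   values may be negative unless clamped): same genes, cells and order as
#'   `x_query`; attribute `"beta"` holds the m x n coefficient matrix.
#' @export
project_batch <- function(x_query, Xc_query, Xc_ref,
                          clamp_nonnegative = FALSE) {
  stopifnot(inherits(x_query, "expr_mat"))
  Xc_query <- as.matrix(Xc_query)
  Xc_ref <- as.matrix(Xc_ref)
  p <- nrow(x_query$values)
  if (nrow(Xc_query) != p || nrow(Xc_ref) != p)
    stop("centroid matrices must have one row per gene of the query batch")
  if (ncol(Xc_query) != ncol(Xc_ref))
    stop("Xc_query and Xc_ref must have the same number of columns")
  if (ncol(Xc_query) < 1L) stop("need at least one putative pair to project")
  if (all(Xc_query == 0)) stop("Xc_query is all zero; cannot decompose cells")

  s <- svd(Xc_query)
  tol <- max(dim(Xc_query)) * .Machine$double.eps * s$d[1L]
  pos <- s$d > tol
  # minimum-norm least squares: beta = V D^+ U' X
  beta <- s$v[, pos, drop = FALSE] %*%
    ((t(s$u[, pos, drop = FALSE]) %*% x_query$values) / s$d[pos])
  values <- Xc_ref %*% beta
  if (clamp_nonnegative) values <- pmax(values, 0)
  dimnames(values) <- dimnames(x_query$values)
  dimnames(beta) <- list(colnames(Xc_query), cell_ids(x_query))
  structure(list(values = values, batch_id = x_query$batch_id),
            class = c("corrected_mat", "expr_mat"),
            beta = beta)
}

#' @export
print.corrected_mat <- function(x, ...) {
  cat(sprintf("<corrected_mat> batch '%s': %d genes x %d cells (projected)\n",
              x$batch_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}
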