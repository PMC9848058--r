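#' Local inverse Simpson index (LISI)
#'
#' For each cell, Gaussian kernel weights over its nearest neighbours are
#' calibrated by binary search on the kernel bandwidth until the weight
#' distribution's entropy equals `log(perplexity)`; the cell's score is the
#' inverse Simpson index `1 / sum_t q(t)^2` of the weight-aggregated label
#' proportions `q(t)`. A score of 1 means the neighbourhood is pure (one
#' label); the score can never exceed the number of distinct labels. With
#' cell-type labels a mean near 1 indicates high local cell-type purity
#' (the quantity to minimise after batch correction); with batch labels a
#' larger mean indicates better batch mixing.
#'
#' @param embedding cell x d numeric matrix (rows are cells).
#' @param labels per-cell categorical labels (factor or character).
#' @param perplexity effective neighbourhood size (default 30); the
#'   neighbourhood used is the `3 * perplexity` nearest cells, which must
#'   be fewer than the number of cells.
#' @param label_kind stored on the result; `"cell_type"` or `"batch"`.
#' @param tol entropy bisection tolerance (default 1e-5).
#' @param max_iter maximum bisection iterations (default 50).
#' @return Object of class `lisi_result`: list with `per_cell` (scores, one
#'   per cell), `mean`, `by_label` (mean score per label, for per-type
#'   summaries), `perplexity`, `label_kind`.
#' @export
lisi <- function(embedding, labels, perplexity = 30,
                 label_kind = "cell_type", tol = 1e-5, max_iter = 50L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n < 2L) stop("LISI needs at least two cells")
  if (length(labels) != n) stop("one label per cell required")
  if (anyNA(labels)) stop("labels must not contain NA")
  labels <- as.factor(labels)
  k <- as.integer(floor(3 * perplexity))
  if (k >= n)
    stop("perplexity too large: 3*perplexity (", k,
         ") must be below the number of cells (", n, ")")
  if (k < 1L) stop("perplexity too small")

  d2 <- as.matrix(stats::dist(embedding))^2
  nlab <- nlevels(labels)
  lab_int <- as.integer(labels)
  per_cell <- numeric(n)
  log_perp <- log(perplexity)

  for (i in seq_len(n)) {
    ord <- order(d2[i, ])
    ord <- ord[ord != i][seq_len(k)]
    di <- d2[i, ord]
    w <- gaussian_weights(di, log_perp, tol, max_iter)
    q <- vapply(seq_len(nlab), function(t) sum(w[lab_int[ord] == t]),
                numeric(1))
    q <- q / sum(q)   # exact renormalisation: a pure neighbourhood scores 1
    per_cell[i] <- 1 / sum(q^2)
  }
  structure(list(per_cell = per_cell, mean = mean(per_cell),
                 by_label = tapply(per_cell, labels, mean),
                 perplexity = perplexity, label_kind = label_kind),
            class = "lisi_result")
}

# Perplexity-calibrated Gaussian weights over squared distances.
# Bisection on the precision beta so that the Shannon entropy of the
# normalised weights equals log_perp; returns normalised weights.
gaussian_weights <- function(d2, log_perp, tol = 1e-5, max_iter = 50L) {
  if (all(d2 == 0)) return(rep(1 / length(d2), length(d2)))
  beta <- 1
  beta_min <- -Inf
  beta_max <- Inf
  for (iter in seq_len(max_iter)) {
    w <- exp(-d2 * beta)
    sw <- sum(w)
    if (sw == 0) {
      h <- 0
    } else {
      h <- log(sw) + beta * sum(d2 * w) / sw
    }
    diff <- h - log_perp
    if (abs(diff) < tol) break
    if (diff > 0) {            # entropy too high: sharpen
      beta_min <- beta
      beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
    } else {
      beta_max <- beta
      beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
    }
  }
  w <- exp(-d2 * beta)
  if (sum(w) == 0) w <- as.numeric(d2 == min(d2))
  w / sum(w)
}

#' @export
print.lisi_result <- function(x, ...) {
  cat(sprintf("<lisi_result> %s: mean %.4f over %d cells (perplexity %g)\n",
              x$label_kind, x$mean, length(x$per_cell), x$perplexity))
  invisible(x)
}

#' Evaluate a correction with cell-type and batch LISI
#'
#' Concatenates the (corrected) batches, reduces the cells to `d` principal
#' components and computes LISI under both labelings. The cell-type score
#' (cLISI) measures how pure each cell's local neighbourhood is — to be
#' minimised; the batch score measures batch mixing — to be maximised.
#' Requires cell-type labels for all cells, so it is an evaluation-only
#' tool for data with annotations or for simulations.
#'
#' @param batches list of `expr_mat` / `corrected_mat` objects (reference
#'   plus corrected queries) sharing one gene panel.
#' @param cell_types named character vector of cell-type labels (names are
#'   cell ids covering every cell), or an unnamed vector in concatenation
#'   order.
#' @param d number of principal components (default 20; use `0` to skip the
#'   reduction and score raw gene space).
#' @param perplexity LISI perplexity (default 30).
#' @return List with `clisi_celltype` and `lisi_batch`, both
#'   [lisi()] results, plus `embedding` (the PC coordinates) and the label
#'   vectors used.
#' @export
evaluate_correction <- function(batches, cell_types, d = 20, perplexity = 30) {
  if (inherits(batches, "expr_mat")) batches <- list(batches)
  panel <- rownames(batches[[1L]]$values)
  for (b in batches)
    if (!identical(rownames(b$values), panel))
      stop("batches must share an identical gene panel")
  values <- do.call(cbind, lapply(batches, `[[`, "values"))
  batch_lab <- unlist(lapply(batches, function(b)
    rep(as.character(b$batch_id), ncol(b$values))))
  ids <- colnames(values)

  if (!is.null(names(cell_types))) {
    missing <- setdiff(ids, names(cell_types))
    if (length(missing))
      stop("missing cell-type labels for cell(s): ",
           paste(utils::head(missing, 5L), collapse = ", "))
    cell_types <- cell_types[ids]
  } else if (length(cell_types) != ncol(values)) {
    stop("cell_types must be named by cell id or match the total cell count")
  }

  emb <- t(values)
  if (d > 0) {
    d <- min(d, nrow(emb) - 1L, ncol(emb))
    emb <- stats::prcomp(emb, rank. = d, center = TRUE, scale. = FALSE)$x
  }
  res_ct <- lisi(emb, cell_types, perplexity, label_kind = "cell_type")
  res_b <- lisi(emb, batch_lab, perplexity, label_kind = "batch")
  stopifnot(all(res_ct$per_cell <= length(unique(cell_types)) + 1e-8),
            all(res_b$per_cell <= length(unique(batch_lab)) + 1e-8))
  list(clisi_celltype = res_ct, lisi_batch = res_b,
       embedding = emb, cell_types = as.character(cell_types),
       batches = batch_lab)
}

#' Write per-cell evaluation scores to a TSV file
#'
#' @param eval result of [evaluate_correction()].
#' @param path output TSV path (columns cell_id, batch, cell_type,
#'   clisi_celltype, lisi_batch).
#' @return `path`, invisibly.
#' @export
write_evaluation_tsv <- function(eval, path) {
  df <- data.frame(cell_id = rownames(eval$embedding),
                   batch = eval$batches,
                   cell_type = eval$cell_types,
                   clisi_celltype = eval$clisi_celltype$per_cell,
                   lisi_batch = eval$lisi_batch$per_cell)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
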