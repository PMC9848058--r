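#' Expression matrix for a single batch
#'
#' A light container for log-normalised gene-by-cell expression from one
#' batch. All batches in an integration run must share an identical,
#' identically ordered gene panel; gene and cell identifiers are carried as
#' the dimnames of `values`.
#'
#' @param values numeric gene x cell matrix of finite, non-negative
#'   log-expression values.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `rownames(values)`).
#' @param cell_ids character vector of cell identifiers, unique within the
#'   batch (defaults to `colnames(values)`).
#' @param batch_id single label identifying the batch.
#'
#' @return An object of class `expr_mat`: a list with elements `values`
#'   (dimnamed matrix) and `batch_id`.
#' @export
#' @examples
#' m <- matrix(abs(rnorm(20)), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' x <- expression_matrix(m, batch_id = "b0")
#' dim(x)
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values), batch_id) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene and cell identifiers are required (dimnames or arguments)")
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique within a batch")
  if (!all(is.finite(values))) stop("expression values must all be finite")
  if (any(values < 0)) stop("expression values must be non-negative")
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(gene_ids), as.character(cell_ids))
  structure(list(values = values, batch_id = batch_id), class = "expr_mat")
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> batch '%s': %d genes x %d cells\n",
              x$batch_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Gene identifiers of an expression matrix
#' @param x an `expr_mat`.
#' @return Character vector of gene ids, in panel order.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Cell identifiers of an expression matrix
#' @param x an `expr_mat`.
#' @return Character vector of cell ids.
#' @export
cell_ids <- function(x) colnames(x$values)

#' Depth-normalise and log-transform a count matrix
#'
#' Divides each cell's counts by its sequencing depth (column sum), rescales
#' to a common library size and applies `log(1 + x)`. This is the standard
#' per-10k log-normalisation and produces the input representation the
#' integration pipeline assumes. Data that are already depth-normalised and
#' log-transformed can bypass this step entirely.
#'
#' @param counts non-negative gene x cell count matrix with gene row names
#'   and cell column names.
#' @param scale library-size scaling factor (default 10000).
#' @param batch_id batch label attached to the result.
#' @return An [expression_matrix()] with
#'   `value[i, j] = log(1 + scale * counts[i, j] / depth[j])`.
#' @export
#' @examples
#' cnt <- matrix(rpois(20, 5), 4, 5,
#'               dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' normalize_and_log(cnt, scale = 1e4, batch_id = "b0")
normalize_and_log <- function(counts, scale = 1e4, batch_id = "batch") {
  counts <- as.matrix(counts)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a single positive number")
  if (any(counts < 0)) stop("counts must be non-negative")
  depth <- colSums(counts)
  if (any(depth == 0)) {
    bad <- colnames(counts)[depth == 0]
    if (is.null(bad)) bad <- which(depth == 0)
    stop("cell(s) with all-zero counts: ", paste(bad, collapse = ", "))
  }
  values <- log1p(sweep(counts, 2L, depth, "/") * scale)
  expression_matrix(values, batch_id = batch_id)
}

#' Per-batch highly variable genes, unioned across batches
#'
#' Ranks genes within each batch by the variance of their log-normalised
#' expression, takes the top `m` per batch and returns the union. Genes not
#' highly variable in any batch are thereby discarded. The returned ids keep
#' the order of the shared gene panel, so subsetting every batch by the
#' result leaves all batches identically ordered.
#'
#' @param batches list of [expression_matrix()] objects sharing one gene
#'   panel.
#' @param m number of top-variance genes to keep per batch (default 2000).
#' @return Character vector of gene ids (subset of the panel, panel order).
#' @export
select_hvg_union <- function(batches, m = 2000) {
  if (inherits(batches, "expr_mat")) batches <- list(batches)
  if (!length(batches)) stop("need at least one batch")
  if (!is.numeric(m) || length(m) != 1L || m <= 0)
    stop("m must be a single positive integer")
  panel <- gene_ids(batches[[1L]])
  for (b in batches) {
    if (!identical(gene_ids(b), panel))
      stop("all batches must share an identical, identically ordered gene panel")
  }
  m <- min(as.integer(m), length(panel))
  keep <- logical(length(panel))
  for (b in batches) {
    v <- row_vars(b$values)
    keep[order(v, decreasing = TRUE)[seq_len(m)]] <- TRUE
  }
  panel[keep]
}

#' Restrict batches to a gene subset
#'
#' @param x an `expr_mat` or a list of them.
#' @param genes gene ids to keep; the result follows the order of `genes`,
#'   so subsetting several batches by one vector aligns their panels.
#' @return Object(s) of the same shape restricted to `genes`.
#' @export
subset_genes <- function(x, genes) {
  if (is.list(x) && !inherits(x, "expr_mat"))
    return(lapply(x, subset_genes, genes = genes))
  missing <- setdiff(genes, gene_ids(x))
  if (length(missing))
    stop("genes not in panel: ", paste(utils::head(missing, 5L), collapse = ", "))
  expression_matrix(x$values[genes, , drop = FALSE], batch_id = x$batch_id)
}

# per-gene sample variance of a genes x cells matrix
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(0, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}
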