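#' Read a batch from Matrix Market files
#'
#' Reads the 10x-style triplet of `matrix.mtx` (genes x cells),
#' `genes.tsv` and `barcodes.tsv` from a directory. The first column of
#' `genes.tsv` is used as the gene identifier.
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @param batch_id batch label attached to the result.
#' @return An [expression_matrix()] (dense).
#' @export
read_expression_mtx <- function(dir, batch_id = basename(dir)) {
  mtx <- file.path(dir, "matrix.mtx")
  gf <- file.path(dir, "genes.tsv")
  bf <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, gf, bf)) if (!file.exists(f)) stop("missing file: ", f)
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- utils::read.table(gf, sep = "\t", header = FALSE,
                             colClasses = "character")[[1L]]
  cells <- utils::read.table(bf, sep = "\t", header = FALSE,
                             colClasses = "character")[[1L]]
  expression_matrix(m, gene_ids = genes, cell_ids = cells, batch_id = batch_id)
}

#' Write a batch as Matrix Market files
#'
#' @param x an `expr_mat`.
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_expression_mtx <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(gene_ids(x), file.path(dir, "genes.tsv"))
  writeLines(cell_ids(x), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a batch from a dense CSV/TSV file
#'
#' Expects genes as rows (first column = gene ids) and a header row of cell
#' identifiers.
#'
#' @param path file path; the separator is inferred from the extension
#'   (`.tsv` means tab, anything else comma) unless `sep` is given.
#' @param batch_id batch label.
#' @param sep field separator override.
#' @return An [expression_matrix()].
#' @export
read_expression_csv <- function(path, batch_id = basename(path), sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                          check.names = FALSE)
  expression_matrix(as.matrix(df), batch_id = batch_id)
}

#' Write a batch as a dense CSV/TSV file
#'
#' @param x an `expr_mat`.
#' @param path output path; separator inferred as in [read_expression_csv()].
#' @param sep field separator override.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(x, path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(x$values, path, sep = sep, quote = FALSE,
                     col.names = NA)
  invisible(path)
}
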