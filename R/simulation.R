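#' Simulate multi-batch log-expression data with planted structure
#'
#' Generates one reference batch plus `n_queries` query batches directly in
#' log-expression space: each cell is its type's mean profile, plus a
#' gene-wise additive batch shift (zero for the reference batch), plus
#' Gaussian noise, clamped at 0. Types share a common per-gene baseline and
#' differ only at their planted marker genes, whose index sets are disjoint
#' across types — so the ground truth for marker recovery and for
#' cross-batch cluster matching is known exactly. Batch-private types are
#' obtained by setting a type's proportion to zero in some batches.
#'
#' @param n_genes gene panel size (default 500).
#' @param n_types number of planted cell types (default 4, >= 2).
#' @param n_queries number of query batches (default 1; total batches is
#'   `n_queries + 1`).
#' @param n_per_batch cells per batch; single number or one per batch
#'   (reference first). Default 300 each.
#' @param type_proportions per-batch type proportions: vector of length
#'   `n_types` (recycled across batches) or a list with one vector per
#'   batch, each summing to 1. Zero entries make a type absent from that
#'   batch. Default: equal proportions everywhere.
#' @param markers_per_type planted marker genes per type (default 15).
#' @param marker_effect additive log-expression elevation of a type's
#'   markers over baseline (default 2).
#' @param batch_effect_sd sd of the gene-wise additive batch shift in log
#'   space (default 1; 0 gives batches drawn from one distribution).
#' @param noise_sd sd of the per-cell Gaussian noise (default 0.5).
#' @param baseline_range range of the shared per-gene baseline expression,
#'   drawn uniformly (default `c(0.5, 2)`).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return List with `batches` (list of [expression_matrix()], reference
#'   `"batch0"` first) and `truth`, an object of class `sim_truth`: list
#'   with `type_means` (gene x T), `batch_shifts` (gene x (B+1), reference
#'   column all zero), `cell_type_of` and `batch_of` (named by cell id),
#'   `marker_genes_of_type` (list of gene-id vectors) and `seed`.
#' @export
simulate_batches <- function(n_genes = 500, n_types = 4, n_queries = 1,
                             n_per_batch = 300, type_proportions = NULL,
                             markers_per_type = 15, marker_effect = 2,
                             batch_effect_sd = 1, noise_sd = 0.5,
                             baseline_range = c(0.5, 2), seed = 1L) {
  if (n_types < 2) stop("need at least two cell types")
  if (n_types * markers_per_type > n_genes)
    stop("gene panel too small for the requested planted markers")
  n_batches <- n_queries + 1L
  if (length(n_per_batch) == 1L) n_per_batch <- rep(n_per_batch, n_batches)
  if (length(n_per_batch) != n_batches)
    stop("n_per_batch must have one entry per batch")

  if (is.null(type_proportions))
    type_proportions <- rep(1 / n_types, n_types)
  if (!is.list(type_proportions))
    type_proportions <- rep(list(type_proportions), n_batches)
  if (length(type_proportions) != n_batches)
    stop("type_proportions must give one vector per batch")
  for (pr in type_proportions) {
    if (length(pr) != n_types || any(pr < 0) ||
        abs(sum(pr) - 1) > 1e-8)
      stop("each batch's type proportions must be length n_types, ",
           "non-negative and sum to 1")
  }

  set.seed(as.integer(seed))
  genes <- sprintf("gene%d", seq_len(n_genes))
  types <- sprintf("type%d", seq_len(n_types))
  baseline <- stats::runif(n_genes, baseline_range[1L], baseline_range[2L])

  marker_idx <- split(seq_len(n_types * markers_per_type),
                      rep(seq_len(n_types), each = markers_per_type))
  type_means <- matrix(baseline, n_genes, n_types,
                       dimnames = list(genes, types))
  for (t in seq_len(n_types))
    type_means[marker_idx[[t]], t] <- type_means[marker_idx[[t]], t] +
      marker_effect

  batch_names <- sprintf("batch%d", seq_len(n_batches) - 1L)
  batch_shifts <- matrix(0, n_genes, n_batches,
                         dimnames = list(genes, batch_names))
  if (n_batches > 1L && batch_effect_sd > 0)
    batch_shifts[, -1L] <- stats::rnorm(n_genes * (n_batches - 1L),
                                        sd = batch_effect_sd)

  comp <- lapply(seq_len(n_batches), function(b)
    proportions_to_counts(type_proportions[[b]], n_per_batch[b]))
  sim <- simulate_core(type_means, batch_shifts, comp, noise_sd)
  sim$truth$marker_genes_of_type <-
    stats::setNames(lapply(marker_idx, function(i) genes[i]), types)
  sim$truth$seed <- as.integer(seed)
  sim
}

# largest-remainder apportionment of n cells to proportions
proportions_to_counts <- function(prop, n) {
  raw <- prop * n
  cnt <- floor(raw)
  short <- n - sum(cnt)
  if (short > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[extra] <- cnt[extra] + 1L
  }
  as.integer(cnt)
}

# shared generator: type_means gene x T, batch_shifts gene x B_total,
# composition = list of per-batch integer count vectors over types
simulate_core <- function(type_means, batch_shifts, composition, noise_sd) {
  genes <- rownames(type_means)
  types <- colnames(type_means)
  batch_names <- colnames(batch_shifts)
  batches <- vector("list", length(batch_names))
  cell_type_of <- character(0)
  batch_of <- character(0)
  for (b in seq_along(batch_names)) {
    cnt <- composition[[b]]
    lab <- rep(seq_along(cnt), cnt)
    n_b <- length(lab)
    mu <- type_means[, lab, drop = FALSE] + batch_shifts[, b]
    vals <- pmax(mu + stats::rnorm(length(mu), sd = noise_sd), 0)
    cells <- sprintf("b%d_c%d", b - 1L, seq_len(n_b))
    dimnames(vals) <- list(genes, cells)
    batches[[b]] <- expression_matrix(vals, batch_id = batch_names[b])
    cell_type_of <- c(cell_type_of, stats::setNames(types[lab], cells))
    batch_of <- c(batch_of, stats::setNames(rep(batch_names[b], n_b), cells))
  }
  names(batches) <- batch_names
  truth <- structure(list(type_means = type_means,
                          batch_shifts = batch_shifts,
                          cell_type_of = cell_type_of,
                          batch_of = batch_of,
                          marker_genes_of_type = NULL,
                          seed = NA_integer_),
                     class = "sim_truth")
  list(batches = batches, truth = truth)
}

#' Two-batch scenario with similar batch-private cell types
#'
#' Emulates the structure of a two-batch dendritic-cell experiment: both
#' batches contain 96 cells of each of two shared types, and each batch
#' additionally contains 96 cells of a type private to it. The two private
#' types are deliberately given similar mean profiles (their planted marker
#' sets overlap in 10 of 15 genes), which creates the hard case for batch
#' correction: an aggressive method that aligns every cluster across
#' batches will merge the two private types, while a correct method keeps
#' them separated.
#'
#' @param seed integer seed.
#' @param n_genes gene panel size (default 500).
#' @param batch_effect_sd,noise_sd,marker_effect as in
#'   [simulate_batches()].
#' @return As [simulate_batches()]: `batches` (reference `"batch0"` with
#'   types type1, type2 and private1; query `"batch1"` with type1, type2
#'   and private2; 3 x 96 cells each) and `truth`. The private types'
#'   marker sets are intentionally overlapping, not disjoint.
#' @export
dataset3_scenario <- function(seed = 1L, n_genes = 500, batch_effect_sd = 1,
                              noise_sd = 0.5, marker_effect = 2) {
  set.seed(as.integer(seed))
  genes <- sprintf("gene%d", seq_len(n_genes))
  types <- c("type1", "type2", "private1", "private2")
  baseline <- stats::runif(n_genes, 0.5, 2)
  marker_idx <- list(type1 = 1:15, type2 = 16:30,
                     private1 = 31:45, private2 = 36:50)
  type_means <- matrix(baseline, n_genes, 4,
                       dimnames = list(genes, types))
  for (t in seq_along(types))
    type_means[marker_idx[[t]], t] <- type_means[marker_idx[[t]], t] +
      marker_effect
  batch_shifts <- matrix(0, n_genes, 2,
                         dimnames = list(genes, c("batch0", "batch1")))
  batch_shifts[, 2L] <- stats::rnorm(n_genes, sd = batch_effect_sd)
  composition <- list(c(96L, 96L, 96L, 0L), c(96L, 96L, 0L, 96L))
  sim <- simulate_core(type_means, batch_shifts, composition, noise_sd)
  sim$truth$marker_genes_of_type <-
    stats::setNames(lapply(marker_idx, function(i) genes[i]), types)
  sim$truth$seed <- as.integer(seed)
  sim
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d genes, %d types, %d batches, %d cells (seed %d)\n",
              nrow(x$type_means), ncol(x$type_means), ncol(x$batch_shifts),
              length(x$cell_type_of), x$seed))
  invisible(x)
}
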