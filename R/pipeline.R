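#' Configuration for an integration run
#'
#' Bundles the tunable parameters of the four-step correction. The
#' defaults are the method's standard settings, used unchanged across
#' datasets: cluster count from the square-root rule on the reference
#' batch size, `h = 75` marker genes per cluster and `omega = 0.5` of
#' matched pairs kept as putative.
#'
#' @param k number of clusters per batch, or `"auto"` for
#'   [default_k()] on the reference batch size.
#' @param k_multiplier multiplier for the `"auto"` rule (default 1).
#' @param h marker genes per cluster (default 75).
#' @param omega proportion of matched pairs kept as putative, in `(0, 1]`
#'   (default 0.5); interpretable as the proportion of query cells whose
#'   type is shared with the reference.
#' @param seed integer seed for the k-means clustering (default 0).
#' @param hvg_m `"skip"` (default; data are used as supplied) or an
#'   integer: per-batch highly-variable-gene count for
#'   [select_hvg_union()] preprocessing applied to every batch.
#' @param clamp_nonnegative clamp corrected values at 0 (default `FALSE`).
#' @return Object of class `integration_config`.
#' @export
integration_config <- function(k = "auto", k_multiplier = 1, h = 75,
                               omega = 0.5, seed = 0L, hvg_m = "skip",
                               clamp_nonnegative = FALSE) {
  if (!(identical(k, "auto") || (is.numeric(k) && length(k) == 1L && k >= 2)))
    stop("k must be \"auto\" or a single integer >= 2")
  if (!is.numeric(k_multiplier) || k_multiplier <= 0)
    stop("k_multiplier must be positive")
  if (!is.numeric(h) || length(h) != 1L || h < 1) stop("h must be >= 1")
  if (!is.numeric(omega) || omega <= 0 || omega > 1)
    stop("omega must lie in (0, 1]")
  if (!(identical(hvg_m, "skip") ||
        (is.numeric(hvg_m) && length(hvg_m) == 1L && hvg_m >= 1)))
    stop("hvg_m must be \"skip\" or a single positive integer")
  structure(list(k = k, k_multiplier = k_multiplier, h = as.integer(h),
                 omega = omega, seed = as.integer(seed), hvg_m = hvg_m,
                 clamp_nonnegative = isTRUE(clamp_nonnegative)),
            class = "integration_config")
}

#' @export
print.integration_config <- function(x, ...) {
  cat(sprintf(
    "<integration_config> k=%s (x%g), h=%d, omega=%g, seed=%d, hvg=%s%s\n",
    as.character(x$k), x$k_multiplier, x$h, x$omega, x$seed,
    as.character(x$hvg_m), if (x$clamp_nonnegative) ", clamped" else ""))
  invisible(x)
}

#' Integrate query batches onto an untouched reference batch
#'
#' Runs the full four-step correction for each query batch against one
#' reference batch: (1) k-means over-clustering of each batch separately,
#' (2) per-cluster marker genes by Welch t-test within the batch, (3)
#' matching of query clusters to reference clusters by marker overlap,
#' scored with a one-sided Fisher exact test and cut to the `omega`
#' proportion of putative pairs, and (4) least-squares projection of every
#' query cell onto the matched reference centroids. The reference batch is
#' returned untouched; each query's corrected output depends only on the
#' reference, that query, the configuration and the seed, so batches can
#' be added incrementally without changing earlier results. The reference
#' is clustered once and reused for all queries.
#'
#' @param reference the reference [expression_matrix()].
#' @param queries a query `expr_mat` or a list of them.
#' @param config an [integration_config()].
#' @param verbose emit per-stage progress messages (default `FALSE`).
#' @return Object of class `integration_result`: list with `reference`
#'   (identical to the input, after any configured preprocessing),
#'   `corrected` (named list of [project_batch()] outputs, one per query),
#'   `matches` (combined matched-pair table), `ref_assignment`,
#'   `query_assignments`, `config` and `log` (per-query cluster/pair
#'   counts).
#' @export
#' @examples
#' sim <- simulate_batches(n_genes = 120, n_types = 3, n_per_batch = 90,
#'                         markers_per_type = 8, seed = 7)
#' res <- integrate_batches(sim$batches[[1]], sim$batches[-1],
#'                          integration_config(seed = 7))
#' res
integrate_batches <- function(reference, queries,
                              config = integration_config(),
                              verbose = FALSE) {
  stopifnot(inherits(reference, "expr_mat"),
            inherits(config, "integration_config"))
  if (inherits(queries, "expr_mat")) queries <- list(queries)
  if (!length(queries)) stop("need at least one query batch")
  say <- function(...) if (verbose) message(sprintf(...))

  # gene-panel reconciliation
  panels <- lapply(c(list(reference), queries), function(b) gene_ids(b))
  if (!all(vapply(panels, identical, logical(1), panels[[1L]]))) {
    shared <- Reduce(intersect, panels)
    if (length(shared) < 50)
      stop("gene panels disagree and their intersection has fewer than 50 genes")
    warning("batches disagree on gene panels; intersecting to ",
            length(shared), " shared genes")
    reference <- subset_genes(reference, shared)
    queries <- lapply(queries, subset_genes, genes = shared)
  }

  if (!identical(config$hvg_m, "skip")) {
    hvg <- select_hvg_union(c(list(reference), queries), m = config$hvg_m)
    say("preprocessing: %d highly variable genes retained", length(hvg))
    reference <- subset_genes(reference, hvg)
    queries <- lapply(queries, subset_genes, genes = hvg)
  }
  panel <- gene_ids(reference)
  h <- min(config$h, length(panel))

  n0 <- ncol(reference$values)
  K <- if (identical(config$k, "auto"))
    default_k(n0, config$k_multiplier) else as.integer(config$k)

  say("step 1: clustering reference (%d cells, K=%d)", n0, min(K, n0))
  ref_assign <- cluster_batch(reference, min(K, n0), seed = config$seed)
  ref_markers <- all_marker_sets(reference, ref_assign, h = h)

  corrected <- vector("list", length(queries))
  assignments <- vector("list", length(queries))
  all_pairs <- vector("list", length(queries))
  logs <- vector("list", length(queries))

  for (i in seq_along(queries)) {
    q <- queries[[i]]
    K_q <- min(K, ncol(q$values))
    say("batch '%s': step 1 clustering (%d cells, K=%d)",
        q$batch_id, ncol(q$values), K_q)
    q_assign <- cluster_batch(q, K_q, seed = config$seed)
    say("batch '%s': step 2 markers (h=%d)", q$batch_id, h)
    q_markers <- all_marker_sets(q, q_assign, h = h)
    say("batch '%s': step 3 matching", q$batch_id)
    pairs <- match_clusters(q_markers, ref_markers, panel)
    pairs <- putative_matches(pairs, config$omega)
    say("batch '%s': %d pairs, %d putative", q$batch_id,
        nrow(pairs), sum(pairs$putative))
    cm <- centroid_pair_matrices(q_assign, ref_assign, pairs)
    say("batch '%s': step 4 projection on %d centroid pairs",
        q$batch_id, ncol(cm$Xc_query))
    corrected[[i]] <- project_batch(q, cm$Xc_query, cm$Xc_ref,
                                    clamp_nonnegative = config$clamp_nonnegative)
    assignments[[i]] <- q_assign
    all_pairs[[i]] <- pairs
    logs[[i]] <- list(batch = q$batch_id, clusters = q_assign$K,
                      testable = sum(vapply(q_markers, `[[`, logical(1),
                                            "testable")),
                      pairs = nrow(pairs), putative = sum(pairs$putative))
  }
  qids <- vapply(queries, function(q) as.character(q$batch_id), character(1))
  names(corrected) <- names(assignments) <- names(all_pairs) <- qids

  structure(list(reference = reference, corrected = corrected,
                 matches = do.call(rbind, all_pairs),
                 ref_assignment = ref_assign,
                 query_assignments = assignments,
                 config = config, log = logs),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("<integration_result> reference '%s' (%d genes x %d cells), %d quer%s corrected\n",
              x$reference$batch_id, nrow(x$reference$values),
              ncol(x$reference$values), length(x$corrected),
              if (length(x$corrected) == 1L) "y" else "ies"))
  for (l in x$log)
    cat(sprintf("  %s: %d clusters, %d testable, %d/%d putative pairs\n",
                l$batch, l$clusters, l$testable, l$putative, l$pairs))
  invisible(x)
}

#' Write an integration result to disk
#'
#' Writes the corrected query batches (and a passthrough copy of the
#' untouched reference) in MTX or CSV format, plus the matched-pair table.
#'
#' @param result an [integrate_batches()] result.
#' @param dir output directory.
#' @param format `"mtx"` or `"csv"`.
#' @return `dir`, invisibly.
#' @export
write_integration_result <- function(result, dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_b <- c(list(result$reference), unname(result$corrected))
  for (b in all_b) {
    if (format == "mtx") {
      write_expression_mtx(b, file.path(dir, as.character(b$batch_id)))
    } else {
      write_expression_csv(b, file.path(dir, paste0(b$batch_id, ".csv")))
    }
  }
  write_matches_tsv(result$matches, file.path(dir, "matched_pairs.tsv"))
  invisible(dir)
}
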