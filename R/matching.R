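#' Marker-overlap contingency table for a cluster pair
#'
#' Forms the 2x2 table used to score a (query cluster, reference cluster)
#' pair: each gene of the shared panel is classified by membership in the
#' query cluster's marker set (rows) and in the reference cluster's marker
#' set (columns).
#'
#' @param query_markers,ref_markers [marker_genes()] results.
#' @param panel the shared gene panel as a character vector, or its size as
#'   a single integer (membership can then not be checked).
#' @return Integer vector `c(a, b, c, d)`: `a` genes in both sets, `b`
#'   query-only, `c` reference-only, `d` in neither; `a+b+c+d` equals the
#'   panel size.
#' @export
overlap_table <- function(query_markers, ref_markers, panel) {
  qg <- query_markers$genes
  rg <- ref_markers$genes
  if (is.character(panel)) {
    p <- length(panel)
    out <- setdiff(c(qg, rg), panel)
    if (length(out))
      stop("marker gene(s) not in panel: ",
           paste(utils::head(out, 5L), collapse = ", "))
  } else {
    p <- as.integer(panel)
    if (length(qg) + length(rg) - length(intersect(qg, rg)) > p)
      stop("marker sets larger than the stated panel size")
  }
  a <- length(intersect(qg, rg))
  b <- length(qg) - a
  c_ <- length(rg) - a
  c(a = a, b = b, c = c_, d = p - a - b - c_)
}

#' One-sided Fisher exact test for marker-set enrichment
#'
#' Upper-tail hypergeometric probability `P[X >= a]` for a 2x2 table
#' `(a, b, c, d)`: the chance of drawing at least `a` of the reference
#' cluster's `a + c` markers when `a + b` genes are sampled without
#' replacement from a panel of `a + b + c + d`. One-sided in the enrichment
#' direction: the score ranks pairs by strength of marker sharing, and a
#' two-sided test would let marker depletion look significant.
#'
#' @param table 2x2 table as a matrix or a length-4 vector `(a, b, c, d)`.
#' @return The p-value in `[0, 1]`.
#' @export
#' @examples
#' fisher_one_sided(c(2, 0, 0, 8))  # identical 2-gene sets in a 10-gene panel: 1/45
fisher_one_sided <- function(table) {
  v <- as.vector(as.matrix(table))
  if (length(v) != 4L) stop("expected a 2x2 table")
  if (any(v < 0)) stop("table entries must be non-negative")
  if (any(v != round(v))) stop("table entries must be integers")
  a <- v[1L]; b <- v[2L]; c_ <- v[3L]; d <- v[4L]
  # population a+b+c+d, successes a+c, draws a+b
  stats::phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
}

#' Match query clusters to reference clusters by marker overlap
#'
#' Each testable query cluster is paired with the reference cluster sharing
#' the largest number of marker genes with it; the pair is scored with
#' [fisher_one_sided()] on its [overlap_table()]. Overlap ties are broken
#' by smaller Fisher p, then by lower reference cluster index. The map is
#' many-to-one by design: over-clustering makes several query clusters per
#' reference cluster expected. Untestable (empty) marker sets yield no pair.
#'
#' @param query_markersets,ref_markersets lists of [marker_genes()] results
#'   (one per cluster).
#' @param panel shared gene panel (character vector) or its size.
#' @return A data frame of matched pairs with columns `query_batch`,
#'   `query_cluster`, `ref_cluster`, `overlap`, `a`, `b`, `c`, `d`,
#'   `p_value` and `putative` (all `NA` until [putative_matches()] is
#'   applied).
#' @export
match_clusters <- function(query_markersets, ref_markersets, panel) {
  q_ok <- Filter(function(m) isTRUE(m$testable), query_markersets)
  r_ok <- Filter(function(m) isTRUE(m$testable), ref_markersets)
  if (!length(r_ok)) stop("no testable reference clusters to match against")
  if (!length(q_ok)) stop("no testable query clusters to match")

  rows <- lapply(q_ok, function(qm) {
    tabs <- lapply(r_ok, function(rm) overlap_table(qm, rm, panel))
    ov <- vapply(tabs, `[[`, integer(1), "a")
    cand <- which(ov == max(ov))
    if (length(cand) > 1L) {
      pc <- vapply(tabs[cand], fisher_one_sided, numeric(1))
      ridx <- vapply(r_ok[cand], `[[`, integer(1), "cluster_id")
      cand <- cand[order(pc, ridx)][1L]
    }
    tab <- tabs[[cand]]
    data.frame(query_batch = qm$batch_id,
               query_cluster = qm$cluster_id,
               ref_cluster = r_ok[[cand]]$cluster_id,
               overlap = tab[["a"]],
               a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]],
               p_value = fisher_one_sided(tab),
               putative = NA)
  })
  do.call(rbind, rows)
}

#' Flag the putative matches among matched pairs
#'
#' Not every matched pair is trustworthy: cell types private to the query
#' batch have no counterpart in the reference, and their forced matches
#' carry large Fisher p-values. Keeping only the `omega` proportion of
#' pairs with the smallest p-values discards those. `omega` has a direct
#' interpretation as (roughly) the proportion of query cells whose type is
#' also present in the reference. The number kept is
#' `max(1, round_half_up(omega * n_pairs))`; boundary p-value ties are
#' resolved by larger overlap, then input order. Applied per query batch.
#'
#' @param pairs data frame from [match_clusters()].
#' @param omega proportion in `(0, 1]` of pairs to keep (default 0.5).
#' @return `pairs` with the `putative` column set, input order preserved.
#' @export
putative_matches <- function(pairs, omega = 0.5) {
  if (!is.data.frame(pairs) || !nrow(pairs)) stop("pairs must be non-empty")
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0 || omega > 1)
    stop("omega must lie in (0, 1]")
  n <- nrow(pairs)
  keep <- max(1L, as.integer(floor(omega * n + 0.5)))
  ord <- order(pairs$p_value, -pairs$overlap, seq_len(n))
  pairs$putative <- FALSE
  pairs$putative[ord[seq_len(keep)]] <- TRUE
  pairs
}

#' Write matched pairs to a TSV file
#'
#' @param pairs data frame from [match_clusters()] / [putative_matches()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_matches_tsv <- function(pairs, path) {
  cols <- c("query_batch", "query_cluster", "ref_cluster", "overlap",
            "p_value", "putative")
  utils::write.table(pairs[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
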