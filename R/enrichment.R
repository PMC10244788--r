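#' Upper-tail hypergeometric test
#'
#' P(X >= k) for X ~ Hypergeometric(N, M, n): the probability of drawing
#' at least `k` members of an M-gene set when sampling `n` genes without
#' replacement from a universe of `N`. Computed in log-space via
#' [stats::phyper()].
#'
#' @param N Universe size.
#' @param M Set size within the universe.
#' @param n Query (draw) size.
#' @param k Observed overlap.
#' @return Upper-tail probability in `(0, 1]`.
#' @export
hypergeom_test <- function(N, M, n, k) {
  if (M > N || n > N) stop("invalid input: M and n must not exceed N")
  if (k > min(M, n)) stop("invalid input: k exceeds min(M, n)")
  if (k < 0 || M < 0 || n < 0) stop("invalid input: negative count")
  stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' Enrich per-path gene lists against gene sets
#'
#' For every (path, set) combination, tests the overlap between the
#' path's genes and the set with the upper-tail hypergeometric test,
#' using the measured genes as the universe (sets are intersected with
#' the universe first). BH adjustment is applied within each path's
#' battery of sets; records passing `p < p_cut` and `FDR < fdr_cut` are
#' flagged retained, and per-set counts of enriched paths are aggregated
#' over retained records.
#'
#' @param query_lists Named list of character vectors (genes per path).
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param universe Character vector of measured gene symbols.
#' @param p_cut,fdr_cut Thresholds (defaults 0.05, 0.1).
#' @return List: `records` (path, set, N, M, n, k, p, fdr, retained) and
#'   `set_path_counts` (enriched-path count per set, descending).
#' @export
enrich_gene_lists <- function(query_lists, gene_sets, universe,
                              p_cut = 0.05, fdr_cut = 0.1) {
  if (length(universe) == 0) stop("empty universe")
  empty <- data.frame(path = character(0), set = character(0),
                      N = integer(0), M = integer(0), n = integer(0),
                      k = integer(0), p = numeric(0), fdr = numeric(0),
                      retained = logical(0))
  if (length(query_lists) == 0) {
    return(list(records = empty, set_path_counts = integer(0)))
  }
  universe <- unique(universe)
  N <- length(universe)
  sets_u <- lapply(gene_sets, intersect, y = universe)

  rec <- lapply(names(query_lists), function(pid) {
    q <- intersect(unique(query_lists[[pid]]), universe)
    n <- length(q)
    df <- data.frame(
      path = pid,
      set = names(sets_u),
      N = N,
      M = vapply(sets_u, length, integer(1)),
      n = n,
      k = vapply(sets_u, function(s) length(intersect(s, q)), integer(1)),
      stringsAsFactors = FALSE
    )
    df$p <- mapply(hypergeom_test, df$N, df$M, df$n, df$k)
    df$fdr <- bh_adjust(df$p)$adjusted
    df$retained <- df$p < p_cut & df$fdr < fdr_cut
    df
  })
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  counts <- table(records$set[records$retained])
  counts <- sort(counts, decreasing = TRUE)
  list(records = records,
       set_path_counts = stats::setNames(as.integer(counts), names(counts)))
}
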