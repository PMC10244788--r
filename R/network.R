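#' Build the differential coexpression network
#'
#' For every gene pair, the Pearson correlation is computed separately in
#' the two phenotype groups with two-sided t-distribution p-values, and
#' p-values are BH-adjusted within each group's full pair family. An edge
#' is retained when the two correlations have opposite signs and both
#' groups individually pass `p < p_cut` and `FDR < fdr_cut`. Genes
#' constant within either group are excluded from pairing.
#'
#' All-pairs correlation is quadratic in the gene count, so matrices
#' larger than `max_genes` are reduced to the `max_genes` most variable
#' genes first.
#'
#' @param study An [expression_study()] with a two-level phenotype.
#' @param p_cut,fdr_cut Per-group thresholds (defaults 0.05, 0.1).
#' @param max_genes Cap on the number of genes correlated (default 3000).
#' @return A `diffcoexp_network`: `nodes`, `edges` (data frame with
#'   per-group r, p, fdr), and a sorted adjacency list.
#' @export
build_diffcoexp_network <- function(study, p_cut = 0.05, fdr_cut = 0.1,
                                    max_genes = 3000) {
  t2dm <- .binary_groups(study$samples$phenotype)
  if (sum(t2dm) < 3 || sum(!t2dm) < 3) {
    stop("need >= 3 samples in each phenotype group")
  }
  m <- study$matrix
  if (nrow(m) > max_genes) {
    v <- apply(m, 1, stats::var)
    m <- m[order(-v)[seq_len(max_genes)], , drop = FALSE]
    m <- m[sort(rownames(m)), , drop = FALSE]
  }
  sd_t <- apply(m[, t2dm, drop = FALSE], 1, stats::sd)
  sd_c <- apply(m[, !t2dm, drop = FALSE], 1, stats::sd)
  keep <- sd_t > 0 & sd_c > 0
  m <- m[keep, , drop = FALSE]
  genes <- rownames(m)
  ng <- length(genes)
  if (ng < 2) stop("fewer than 2 non-constant genes")

  cor_block <- function(cols) {
    x <- t(m[, cols, drop = FALSE])
    n <- nrow(x)
    r <- stats::cor(x)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[r == 1 | r == -1] <- 0
    list(r = r, p = p, n = n)
  }
  bt <- cor_block(t2dm)
  bc <- cor_block(!t2dm)

  ut <- upper.tri(bt$r)
  idx <- which(ut, arr.ind = TRUE)
  p_t <- bt$p[ut]
  p_c <- bc$p[ut]
  fdr_t <- bh_adjust(p_t)$adjusted
  fdr_c <- bh_adjust(p_c)$adjusted
  r_t <- bt$r[ut]
  r_c <- bc$r[ut]
  pass <- sign(r_t) == -sign(r_c) & r_t != 0 &
    p_t < p_cut & p_c < p_cut & fdr_t < fdr_cut & fdr_c < fdr_cut

  edges <- data.frame(gene_a = genes[idx[pass, 1]],
                      gene_b = genes[idx[pass, 2]],
                      r_t2dm = r_t[pass], r_control = r_c[pass],
                      p_t2dm = p_t[pass], p_control = p_c[pass],
                      fdr_t2dm = fdr_t[pass], fdr_control = fdr_c[pass],
                      stringsAsFactors = FALSE)
  # canonical orientation gene_a < gene_b
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  .as_network(genes, edges)
}

.as_network <- function(nodes, edges) {
  nodes <- sort(nodes)
  adj <- vector("list", length(nodes))
  names(adj) <- nodes
  ia <- match(edges$gene_a, nodes)
  ib <- match(edges$gene_b, nodes)
  for (i in seq_along(ia)) {
    adj[[ia[i]]] <- c(adj[[ia[i]]], ib[i])
    adj[[ib[i]]] <- c(adj[[ib[i]]], ia[i])
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  structure(list(nodes = nodes, edges = edges, adj = adj),
            class = "diffcoexp_network")
}

#' Construct a network object from an edge list
#'
#' @param edges Data frame with `gene_a`, `gene_b` columns (extra columns
#'   kept).
#' @param nodes Optional node set (defaults to the genes in `edges`).
#' @return A `diffcoexp_network`.
#' @export
network_from_edges <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- unique(c(edges$gene_a, edges$gene_b))
  .as_network(nodes, edges)
}

#' @export
print.diffcoexp_network <- function(x, ...) {
  cat(sprintf("diffcoexp_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Unit-weight Dijkstra (== breadth-first search) from one source, visiting
# neighbors in lexicographic node order so parents, and hence extracted
# paths, are deterministic.
.bfs_parents <- function(network, source_idx) {
  n <- length(network$nodes)
  parent <- rep(NA_integer_, n)
  dist <- rep(NA_integer_, n)
  dist[source_idx] <- 0L
  queue <- source_idx
  head <- 1L
  while (head <= length(queue)) {
    u <- queue[head]
    head <- head + 1L
    for (v in network$adj[[u]]) {
      if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1L
        parent[v] <- u
        queue <- c(queue, v)
      }
    }
  }
  list(parent = parent, dist = dist)
}

.extract_path <- function(nodes, parent, source_idx, target_idx) {
  path <- target_idx
  while (path[1] != source_idx) path <- c(parent[path[1]], path)
  nodes[path]
}

#' Shortest paths for a set of source-target gene pairs
#'
#' Unweighted shortest paths (every edge weight 1, so Dijkstra reduces to
#' breadth-first search) with lexicographic tie-breaking; exactly one
#' deterministic path is reported per reachable pair. Pairs whose genes
#' are absent from the network or disconnected are listed as unreachable.
#'
#' @param network A `diffcoexp_network`.
#' @param pairs Data frame with `source` and `target` gene columns.
#' @return A `path_set` list: `paths` (list of node sequences, named
#'   "source->target") and `unreachable` (data frame of failed pairs).
#' @export
shortest_paths_for_pairs <- function(network, pairs) {
  paths <- list()
  unreachable <- pairs[0, , drop = FALSE]
  for (src in unique(pairs$source)) {
    sub <- pairs[pairs$source == src, , drop = FALSE]
    si <- match(src, network$nodes)
    bfs <- if (is.na(si)) NULL else .bfs_parents(network, si)
    for (j in seq_len(nrow(sub))) {
      tgt <- sub$target[j]
      ti <- match(tgt, network$nodes)
      if (is.null(bfs) || is.na(ti) || is.na(bfs$dist[ti]) || si == ti) {
        unreachable <- rbind(unreachable, sub[j, , drop = FALSE])
        next
      }
      paths[[paste0(src, "->", tgt)]] <-
        .extract_path(network$nodes, bfs$parent, si, ti)
    }
  }
  rownames(unreachable) <- NULL
  structure(list(paths = paths, unreachable = unreachable),
            class = "path_set")
}

#' Interior betweenness of genes over a path set
#'
#' Counts, for every gene, the number of paths in which it appears as an
#' interior (non-endpoint) node, so a marker is not credited for being a
#' query gene. Sorted by count descending, ties by symbol.
#'
#' @param path_set A `path_set` from [shortest_paths_for_pairs()].
#' @return Data frame: `gene`, `betweenness`.
#' @export
path_betweenness <- function(path_set) {
  interior <- unlist(lapply(path_set$paths, function(p) {
    if (length(p) > 2) p[-c(1, length(p))] else character(0)
  }), use.names = FALSE)
  all_genes <- sort(unique(unlist(path_set$paths, use.names = FALSE)))
  counts <- table(factor(interior, levels = all_genes))
  out <- data.frame(gene = names(counts),
                    betweenness = as.integer(counts),
                    stringsAsFactors = FALSE)
  out[order(-out$betweenness, out$gene), , drop = FALSE]
}

#' Permutation null for top betweenness genes
#'
#' For each evaluated gene, every permutation draws `n_pairs` random
#' source-target node pairs (endpoints exclude the gene itself, since a
#' gene cannot occur inside a path it terminates), recomputes the gene's
#' interior betweenness over the permuted shortest paths, and counts
#' permutations whose value is at least the observed one; `perm_p` is
#' that fraction (no add-one correction, so 0 is possible).
#'
#' @param network A `diffcoexp_network`.
#' @param observed Data frame from [path_betweenness()].
#' @param n_pairs Number of random pairs per permutation (matches the
#'   real pair count).
#' @param n_perm Permutations (default 1000).
#' @param seed Integer seed.
#' @param top_n Evaluate at most this many top-betweenness genes
#'   (default 20); the rest keep `perm_p = NA`.
#' @return `observed` with a `perm_p` column appended.
#' @export
betweenness_null_p <- function(network, observed, n_pairs, n_perm = 1000,
                               seed = 1L, top_n = 20) {
  n <- length(network$nodes)
  if (n_pairs > n * (n - 1) / 2) {
    stop("n_pairs = ", n_pairs, " exceeds the ", n * (n - 1) / 2,
         " available pairs")
  }
  # deterministic BFS parents from every source, computed once
  parents <- lapply(seq_len(n), function(s) .bfs_parents(network, s))
  interior_count <- function(g_idx, src, tgt) {
    cnt <- 0L
    for (j in seq_along(src)) {
      bf <- parents[[src[j]]]
      if (is.na(bf$dist[tgt[j]])) next
      node <- tgt[j]
      while (node != src[j]) {
        par <- bf$parent[node]
        if (node != tgt[j] && node == g_idx) {
          cnt <- cnt + 1L
          break
        }
        node <- par
      }
    }
    cnt
  }
  set.seed(seed)
  observed$perm_p <- NA_real_
  eval_rows <- seq_len(min(top_n, nrow(observed)))
  for (r in eval_rows) {
    g_idx <- match(observed$gene[r], network$nodes)
    pool <- setdiff(seq_len(n), g_idx)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      src <- sample(pool, n_pairs, replace = TRUE)
      tgt <- vapply(src, function(s) {
        cand <- pool[pool != s]
        if (length(cand) == 1) cand else sample(cand, 1)
      }, integer(1))
      if (interior_count(g_idx, src, tgt) >= observed$betweenness[r]) {
        hits <- hits + 1L
      }
    }
    observed$perm_p[r] <- hits / n_perm
  }
  observed
}
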