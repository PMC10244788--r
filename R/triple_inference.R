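#' Select candidate oxidative markers from a GMT file by keyword
#'
#' Takes the union of member genes over all gene sets whose name contains
#' `keyword` (case-insensitive), intersected with the genes measured in
#' the study.
#'
#' @param gmt_path Path to a GMT file.
#' @param universe Character vector of measured gene symbols.
#' @param keyword Keyword to match in set names (default "OXIDATIVE").
#' @return Character vector of candidate gene symbols (sorted).
#' @export
load_gene_sets_by_keyword <- function(gmt_path, universe,
                                      keyword = "OXIDATIVE") {
  sets <- read_gmt(gmt_path)
  hit <- grepl(keyword, names(sets), ignore.case = TRUE)
  if (!any(hit)) {
    warning("no gene set name contains keyword '", keyword, "'")
    return(character(0))
  }
  sort(intersect(unique(unlist(sets[hit], use.names = FALSE)), universe))
}

#' Differential-coexpression test for one gene pair
#'
#' The per-sample product x * y is compared between the phenotype groups
#' with the Kruskal-Wallis test: a pair whose coupling differs between
#' T2DM and control shifts the product's distribution between the groups.
#'
#' @param gene_x,gene_y Expression vectors aligned to the same samples.
#' @param phenotype Binary group vector (two levels).
#' @return A `TestResult` (see [kw_test()]).
#' @export
diffcoexp_test <- function(gene_x, gene_y, phenotype) {
  kw_test(gene_x * gene_y, phenotype)
}

#' Screen all cross-pairs of two marker sets for differential coexpression
#'
#' Runs [diffcoexp_test()] for every pair in `set_a` x `set_b` (self-pairs
#' excluded), applies BH within the full pair family, and flags pairs
#' passing both `p < p_cut` and `FDR < fdr_cut`.
#'
#' @param set_a,set_b Character vectors of gene symbols present in the
#'   study.
#' @param study An [expression_study()].
#' @param p_cut,fdr_cut Retention thresholds (defaults 0.05, 0.1).
#' @return Data frame: `gene_a`, `gene_b`, `p`, `fdr`, `retained`.
#' @export
screen_marker_pairs <- function(set_a, set_b, study,
                                p_cut = 0.05, fdr_cut = 0.1) {
  set_a <- intersect(set_a, rownames(study$matrix))
  set_b <- intersect(set_b, rownames(study$matrix))
  if (length(set_a) == 0 || length(set_b) == 0) {
    warning("empty marker set; returning no pairs")
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      p = numeric(0), fdr = numeric(0),
                      retained = logical(0)))
  }
  pairs <- expand.grid(gene_a = set_a, gene_b = set_b,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
  t2dm <- .binary_groups(study$samples$phenotype)
  m <- study$matrix
  p <- vapply(seq_len(nrow(pairs)), function(i) {
    prod <- m[pairs$gene_a[i], ] * m[pairs$gene_b[i], ]
    if (length(unique(prod)) == 1L) return(1)
    .kw_fast(prod, t2dm)[2]
  }, numeric(1))
  fdr <- bh_adjust(p)$adjusted
  data.frame(pairs, p = p, fdr = fdr,
             retained = p < p_cut & fdr < fdr_cut, row.names = NULL)
}

# Coerces a two-level phenotype vector into logical "is first level of
# T2DM/tumor if present, else first sorted level".
.binary_groups <- function(phenotype) {
  lev <- sort(unique(as.character(phenotype)))
  if (length(lev) != 2) stop("phenotype must have exactly 2 levels")
  pos <- intersect(c("T2DM", "tumor"), lev)
  pos <- if (length(pos) > 0) pos[1] else lev[2]
  as.character(phenotype) == pos
}

#' Permutation test of one differentially coexpressed pair
#'
#' The observed statistic is the absolute difference between the
#' phenotype-group means of the per-sample product x * y. Each
#' permutation replaces `gene_x` with a uniformly drawn measured gene
#' (excluding the pair itself) and recomputes the statistic; the p-value
#' is the fraction of permutations at least as large as the observed
#' value (ties count, no add-one correction, so p may be exactly 0).
#'
#' @param gene_x Symbol of the gene that gets replaced in permutations.
#' @param gene_y Symbol of the fixed partner gene.
#' @param study An [expression_study()] supplying expression for the
#'   replacement candidates.
#' @param pool Candidate replacement genes for the simulated markers.
#'   `NULL` (default) uses every measured gene; passing the marker class
#'   `gene_x` was drawn from (as [assemble_triples()] does) calibrates
#'   the null against that class's shared background signal. At least 10
#'   candidates must remain after excluding the pair.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return Permutation p-value in `[0, 1]`.
#' @export
permutation_pair_test <- function(gene_x, gene_y, study, pool = NULL,
                                  n_perm = 1000, seed = 1L) {
  m <- study$matrix
  if (is.null(pool)) pool <- rownames(m)
  candidates <- setdiff(intersect(pool, rownames(m)), c(gene_x, gene_y))
  if (length(candidates) < 10) {
    stop("replacement pool must contain >= 10 genes besides the pair")
  }
  t2dm <- .binary_groups(study$samples$phenotype)
  w <- ifelse(t2dm, 1 / sum(t2dm), -1 / sum(!t2dm))
  contrast <- m[gene_y, ] * w
  observed <- abs(sum(m[gene_x, ] * contrast))
  all_stats <- abs(as.numeric(m[candidates, , drop = FALSE] %*% contrast))
  set.seed(seed)
  perm <- all_stats[sample.int(length(candidates), n_perm, replace = TRUE)]
  mean(perm >= observed)
}

#' Genome-wide differential-coexpression scan for one marker
#'
#' Tests the marker against every other measured gene with
#' [diffcoexp_test()] and BH-adjusts within this scan (one family per
#' marker).
#'
#' @param marker Gene symbol.
#' @param study An [expression_study()].
#' @return Data frame: `gene`, `p`, `fdr`, ordered by gene symbol.
#' @export
genome_scan <- function(marker, study) {
  m <- study$matrix
  t2dm <- .binary_groups(study$samples$phenotype)
  genes <- sort(setdiff(rownames(m), marker))
  mv <- m[marker, ]
  p <- vapply(genes, function(g) {
    prod <- m[g, ] * mv
    if (length(unique(prod)) == 1L) return(1)
    .kw_fast(prod, t2dm)[2]
  }, numeric(1))
  data.frame(gene = genes, p = unname(p), fdr = bh_adjust(p)$adjusted,
             row.names = NULL)
}

#' Confounder screen for one aging-disease relationship
#'
#' Looks for any other measured gene differentially coexpressed with BOTH
#' the aging marker and the disease marker (p < 0.05 and FDR < 0.1 in
#' each marker's genome-wide scan). If such a gene exists, the
#' aging-to-disease relationship is confounded and the triple is dropped.
#'
#' @param aging_gene,disease_gene Gene symbols.
#' @param scans Named list of [genome_scan()] tables, keyed by marker.
#' @param exclude Gene symbols never considered confounders (the triple's
#'   own genes).
#' @param p_cut,fdr_cut Thresholds (defaults 0.05, 0.1).
#' @return The first qualifying gene symbol (by symbol order), or
#'   `NA_character_` if none.
#' @export
confounder_screen <- function(aging_gene, disease_gene, scans,
                              exclude = character(0),
                              p_cut = 0.05, fdr_cut = 0.1) {
  sa <- scans[[aging_gene]]
  sd_ <- scans[[disease_gene]]
  if (is.null(sa) || is.null(sd_)) stop("missing precomputed scan")
  hit_a <- sa$gene[sa$p < p_cut & sa$fdr < fdr_cut]
  hit_d <- sd_$gene[sd_$p < p_cut & sd_$fdr < fdr_cut]
  both <- setdiff(intersect(hit_a, hit_d),
                  c(exclude, aging_gene, disease_gene))
  if (length(both) == 0) NA_character_ else sort(both)[1]
}

#' Horizontal-pleiotropy screen for one triple
#'
#' Compares the aging-disease association with and without the oxidative
#' marker. With OLS slopes (fitted with intercepts, all samples pooled):
#' residual_A = d - b1 * o, residual_B = a - b2 * o,
#' residual_C = residual_A - b3 * residual_B (the aging-disease relation
#' with the oxidative background removed) and residual_D = d - b4 * a
#' (the direct relation). The per-sample difference
#' residual_C - residual_D is tested between phenotype groups with the
#' Kruskal-Wallis test; a significant difference means the oxidative path
#' carries phenotype-specific information beyond the direct path.
#'
#' @param a,o,d Expression vectors of the aging, oxidative and disease
#'   markers.
#' @param phenotype Binary group vector.
#' @return List: `b` (slopes b1..b4), `residuals` (A-D), `test`
#'   (a `TestResult`), or an error for degenerate regressors.
#' @export
pleiotropy_screen <- function(a, o, d, phenotype) {
  slope <- function(y, x) {
    vx <- stats::var(x)
    if (!is.finite(vx) || vx < 1e-12) {
      stop("degenerate regression: regressor is (nearly) constant")
    }
    stats::cov(x, y) / vx
  }
  b1 <- slope(d, o)
  b2 <- slope(a, o)
  res_a <- d - b1 * o
  res_b <- a - b2 * o
  b3 <- slope(res_a, res_b)
  b4 <- slope(d, a)
  res_c <- res_a - b3 * res_b
  res_d <- d - b4 * a
  list(b = c(b1 = b1, b2 = b2, b3 = b3, b4 = b4),
       residuals = list(A = res_a, B = res_b, C = res_c, D = res_d),
       test = kw_test(res_c - res_d, phenotype))
}

#' Assemble aging-oxidative-disease triples
#'
#' Runs the full integrated screen: (i) differential-coexpression screen
#' of aging x oxidative pairs with BH, (ii) permutation filter replacing
#' the aging marker, (iii) the same screen for oxidative x disease pairs,
#' (iv) permutation filter replacing the oxidative marker, (v) join on
#' the shared oxidative marker into candidate triples (all three genes
#' distinct), (vi) confounder screen of each aging-disease relationship
#' against genome-wide scans, (vii) pleiotropy screen with BH across all
#' surviving triples. A triple is retained only if it passes every
#' filter.
#'
#' @param aging_markers,disease_markers Character vectors (from the
#'   predictors).
#' @param oxidative_candidates Character vector (from
#'   [load_gene_sets_by_keyword()]).
#' @param study An [expression_study()].
#' @param p_cut,fdr_cut,perm_p_cut Thresholds (defaults 0.05, 0.1, 0.05).
#' @param n_perm Permutations per pair (default 1000).
#' @param seed Integer seed for the permutation draws.
#' @param retain_on_significance Pleiotropy retention direction. The
#'   default `FALSE` treats a significant group difference between the
#'   oxidative-routed residual and the direct aging-disease residual as
#'   evidence of horizontal pleiotropy and deletes the triple, matching
#'   the filter's purpose; `TRUE` inverts the rule.
#' @return List: `triples` (one row per candidate triple with all screen
#'   statistics and `retained`), `pairs_ao`, `pairs_od` (screen tables),
#'   `marker_counts` (distinct retained aging/oxidative/disease markers),
#'   `occurrence` (per-gene frequency across retained triples).
#' @export
assemble_triples <- function(aging_markers, disease_markers,
                             oxidative_candidates, study,
                             p_cut = 0.05, fdr_cut = 0.1,
                             perm_p_cut = 0.05, n_perm = 1000, seed = 1L,
                             retain_on_significance = FALSE) {
  empty <- data.frame(aging = character(0), oxidative = character(0),
                      disease = character(0))
  if (length(aging_markers) == 0 || length(disease_markers) == 0 ||
      length(oxidative_candidates) == 0) {
    warning("empty marker list; no triples to assemble")
    return(list(triples = empty, pairs_ao = NULL, pairs_od = NULL,
                marker_counts = c(aging = 0, oxidative = 0, disease = 0),
                occurrence = NULL))
  }

  pairs_ao <- screen_marker_pairs(aging_markers, oxidative_candidates,
                                  study, p_cut, fdr_cut)
  pairs_od <- screen_marker_pairs(oxidative_candidates, disease_markers,
                                  study, p_cut, fdr_cut)

  keep_ao <- pairs_ao[pairs_ao$retained, , drop = FALSE]
  keep_od <- pairs_od[pairs_od$retained, , drop = FALSE]
  # simulated aging markers are drawn from the aging-marker class, and
  # simulated oxidative markers from the oxidative-candidate class, so the
  # null carries the class's shared background signal; small pools fall
  # back to the whole genome
  pool_a <- if (length(aging_markers) >= 12) aging_markers else NULL
  pool_o <- if (length(oxidative_candidates) >= 12) oxidative_candidates
            else NULL
  keep_ao$perm_p <- vapply(seq_len(nrow(keep_ao)), function(i) {
    permutation_pair_test(keep_ao$gene_a[i], keep_ao$gene_b[i], study,
                          pool = pool_a, n_perm = n_perm, seed = seed + i)
  }, numeric(1))
  keep_od$perm_p <- vapply(seq_len(nrow(keep_od)), function(i) {
    permutation_pair_test(keep_od$gene_a[i], keep_od$gene_b[i], study,
                          pool = pool_o, n_perm = n_perm,
                          seed = seed + 10000L + i)
  }, numeric(1))
  keep_ao <- keep_ao[keep_ao$perm_p < perm_p_cut, , drop = FALSE]
  keep_od <- keep_od[keep_od$perm_p < perm_p_cut, , drop = FALSE]

  if (nrow(keep_ao) == 0 || nrow(keep_od) == 0) {
    return(list(triples = empty, pairs_ao = pairs_ao, pairs_od = pairs_od,
                marker_counts = c(aging = 0, oxidative = 0, disease = 0),
                occurrence = NULL))
  }

  tr <- merge(
    stats::setNames(keep_ao[c("gene_a", "gene_b", "p", "fdr", "perm_p")],
                    c("aging", "oxidative", "p_ao", "fdr_ao", "perm_p_ao")),
    stats::setNames(keep_od[c("gene_a", "gene_b", "p", "fdr", "perm_p")],
                    c("oxidative", "disease", "p_od", "fdr_od", "perm_p_od")),
    by = "oxidative")
  tr <- tr[tr$aging != tr$disease & tr$aging != tr$oxidative &
             tr$oxidative != tr$disease, , drop = FALSE]
  tr <- tr[order(tr$aging, tr$oxidative, tr$disease), , drop = FALSE]
  rownames(tr) <- NULL
  if (nrow(tr) == 0) {
    return(list(triples = empty, pairs_ao = pairs_ao, pairs_od = pairs_od,
                marker_counts = c(aging = 0, oxidative = 0, disease = 0),
                occurrence = NULL))
  }

  # genome-wide scans for the confounder stage; BH within each marker's
  # own scan (one family per genome-wide battery)
  scan_markers <- unique(c(tr$aging, tr$disease))
  scans <- lapply(scan_markers, genome_scan, study = study)
  names(scans) <- scan_markers
  tr$confounder_hit <- vapply(seq_len(nrow(tr)), function(i) {
    confounder_screen(tr$aging[i], tr$disease[i], scans,
                      exclude = tr$oxidative[i],
                      p_cut = p_cut, fdr_cut = fdr_cut)
  }, character(1))

  t2dm <- .binary_groups(study$samples$phenotype)
  phen <- ifelse(t2dm, "T2DM", "control")
  m <- study$matrix
  tr$pleiotropy_p <- NA_real_
  for (i in seq_len(nrow(tr))) {
    pl <- tryCatch(
      pleiotropy_screen(m[tr$aging[i], ], m[tr$oxidative[i], ],
                        m[tr$disease[i], ], phen),
      error = function(e) NULL)
    tr$pleiotropy_p[i] <- if (is.null(pl)) NA_real_ else pl$test$p_value
  }
  ok <- !is.na(tr$pleiotropy_p)
  tr$pleiotropy_fdr <- NA_real_
  tr$pleiotropy_fdr[ok] <- bh_adjust(tr$pleiotropy_p[ok])$adjusted

  sig <- ok & tr$pleiotropy_p < p_cut & tr$pleiotropy_fdr < fdr_cut
  pleio_pass <- if (retain_on_significance) sig else (ok & !sig)
  tr$retained <- is.na(tr$confounder_hit) & pleio_pass

  ret <- tr[tr$retained, , drop = FALSE]
  occurrence <- if (nrow(ret) > 0) {
    list(aging = table(ret$aging), oxidative = table(ret$oxidative),
         disease = table(ret$disease))
  } else NULL
  list(triples = tr, pairs_ao = pairs_ao, pairs_od = pairs_od,
       marker_counts = c(aging = length(unique(ret$aging)),
                         oxidative = length(unique(ret$oxidative)),
                         disease = length(unique(ret$disease))),
       occurrence = occurrence)
}
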