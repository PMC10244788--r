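#' Average duplicate tumor profiles from the same patient
#'
#' @param matrix Gene x sample matrix.
#' @param patient_ids Character vector mapping each column to a patient
#'   (e.g. a barcode prefix).
#' @return Matrix with one column per patient (columns named by patient).
#' @export
average_duplicate_patients <- function(matrix, patient_ids) {
  stopifnot(length(patient_ids) == ncol(matrix))
  t(rowsum(t(matrix), group = patient_ids) /
      as.vector(table(patient_ids)))
}

#' Tumor versus normal differential expression
#'
#' Input matrices are assumed log2(x + 1)-scaled; the fold change is
#' computed on the linear scale after inverting that transform. A gene is
#' differentially expressed when fold change > `fc_cut` (or < 1/fc_cut
#' when `two_sided`), Kruskal-Wallis p < `p_cut`, and BH FDR < `fdr_cut`.
#'
#' @param tumor_matrix,normal_matrix Gene x sample matrices with matching
#'   rownames; >= 10 normal samples required.
#' @param fc_cut Fold-change threshold (default 2).
#' @param p_cut,fdr_cut Significance thresholds (defaults 0.05, 0.1).
#' @param two_sided Also call genes with fold change < 1/fc_cut
#'   (default TRUE).
#' @param min_normals Cohort inclusion rule (default 10).
#' @return Data frame: `gene`, `fold_change`, `p`, `fdr`, `is_de`.
#' @export
tumor_normal_de <- function(tumor_matrix, normal_matrix, fc_cut = 2,
                            p_cut = 0.05, fdr_cut = 0.1, two_sided = TRUE,
                            min_normals = 10) {
  if (ncol(normal_matrix) < min_normals) {
    stop("cohort excluded: only ", ncol(normal_matrix),
         " adjacent normal samples (need >= ", min_normals, ")")
  }
  stopifnot(identical(rownames(tumor_matrix), rownames(normal_matrix)))
  lin_t <- 2^tumor_matrix - 1
  lin_n <- 2^normal_matrix - 1
  eps <- 1e-9
  fc <- (rowMeans(lin_t) + eps) / (rowMeans(lin_n) + eps)
  grp <- c(rep(TRUE, ncol(tumor_matrix)), rep(FALSE, ncol(normal_matrix)))
  comb <- cbind(tumor_matrix, normal_matrix)
  p <- apply(comb, 1, function(v) {
    if (length(unique(v)) == 1L) return(1)
    .kw_fast(v, grp)[2]
  })
  fdr <- bh_adjust(p)$adjusted
  fc_pass <- if (two_sided) fc > fc_cut | fc < 1 / fc_cut else fc > fc_cut
  data.frame(gene = rownames(tumor_matrix), fold_change = fc,
             p = unname(p), fdr = fdr,
             is_de = fc_pass & p < p_cut & fdr < fdr_cut,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Split tumor samples by their oxidative-aging marker score
#'
#' The score is the per-sample mean expression over the marker genes;
#' samples scoring above the cohort mean of scores form the "high" group.
#'
#' @param tumor_study An [expression_study()] of tumor samples with
#'   `time`/`event` metadata.
#' @param markers Oxidative-aging marker gene symbols (>= 1 present).
#' @param threshold `"mean"` (default) or `"median"`.
#' @return A `survival_cohort` data frame: `sample_id`, `time`, `event`,
#'   `score`, `group`.
#' @export
survival_group_split <- function(tumor_study, markers,
                                 threshold = c("mean", "median")) {
  threshold <- match.arg(threshold)
  present <- intersect(markers, rownames(tumor_study$matrix))
  if (length(present) == 0) stop("no marker overlaps the expression matrix")
  score <- colMeans(tumor_study$matrix[present, , drop = FALSE])
  cut <- if (threshold == "mean") mean(score) else stats::median(score)
  group <- ifelse(score > cut, "high", "low")
  if (length(unique(group)) < 2) {
    warning("degenerate split: all scores on one side of the threshold")
  }
  out <- data.frame(sample_id = tumor_study$samples$sample_id,
                    time = tumor_study$samples$time,
                    event = tumor_study$samples$event,
                    score = unname(score), group = group,
                    stringsAsFactors = FALSE)
  class(out) <- c("survival_cohort", "data.frame")
  out
}

#' Kaplan-Meier curves and log-rank test for a two-group split
#'
#' Two-group log-rank chi-square (1 df) via [survival::survdiff()] and
#' Kaplan-Meier step functions via [survival::survfit()].
#'
#' @param cohort A `survival_cohort` from [survival_group_split()].
#' @return List: `test` (a `TestResult`), `curves` (data frame of time,
#'   n_risk, survival per group), `zero_event_group` flag.
#' @export
km_logrank <- function(cohort) {
  stopifnot(all(c("time", "event", "group") %in% names(cohort)))
  if (length(unique(cohort$group)) < 2) {
    stop("log-rank needs two groups")
  }
  ev <- tapply(cohort$event, cohort$group, sum)
  zero_event <- any(ev == 0)
  if (zero_event) warning("a group has zero events; p-value is flagged")
  sdiff <- survival::survdiff(
    survival::Surv(time, event) ~ group, data = cohort)
  p <- stats::pchisq(sdiff$chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           data = cohort)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^group=", "", strata),
                       time = fit$time, n_risk = fit$n.risk,
                       survival = fit$surv, stringsAsFactors = FALSE)
  list(test = test_result(unname(sdiff$chisq), p, nrow(cohort)),
       curves = curves, zero_event_group = zero_event)
}

#' Run the pan-cancer stage over a list of cohorts
#'
#' Per cancer: tumor/normal differential expression; survival split on
#' the oxidative-aging marker score with the log-rank test; a
#' tumor-versus-normal differential coexpression network; shortest paths
#' from each marker to each DE gene; enrichment of the path genes; and a
#' summary row. Cancers with fewer than `min_normals` adjacent normals
#' are excluded with a logged reason.
#'
#' @param cohorts Named list; each element is a list with `study` (an
#'   [expression_study()] whose phenotype is tumor/normal and whose tumor
#'   samples carry `time`/`event`).
#' @param markers Oxidative-aging marker symbols.
#' @param gene_sets Named list of gene sets for enrichment.
#' @param p_cut,fdr_cut,fc_cut,min_normals Thresholds.
#' @param network_max_genes Gene cap for the per-cancer network
#'   (default 500).
#' @param max_path_pairs Cap on marker x DE-gene path queries
#'   (default 200).
#' @return List with per-cancer results and a `summary` data frame
#'   (`cancer`, `n_de`, `logrank_p`, `significant`, `excluded`).
#' @export
pancancer_run <- function(cohorts, markers, gene_sets = list(),
                          p_cut = 0.05, fdr_cut = 0.1, fc_cut = 2,
                          min_normals = 10, network_max_genes = 500,
                          max_path_pairs = 200) {
  if (length(cohorts) == 0) stop("empty cohort list")
  results <- list()
  summary_rows <- list()
  for (nm in names(cohorts)) {
    study <- cohorts[[nm]]$study
    is_tumor <- study$samples$phenotype == "tumor"
    n_normal <- sum(!is_tumor)
    if (n_normal < min_normals) {
      summary_rows[[nm]] <- data.frame(
        cancer = nm, n_de = NA_integer_, logrank_p = NA_real_,
        significant = NA, excluded = TRUE,
        reason = paste0("only ", n_normal, " normals"))
      next
    }
    de <- tumor_normal_de(study$matrix[, is_tumor, drop = FALSE],
                          study$matrix[, !is_tumor, drop = FALSE],
                          fc_cut = fc_cut, p_cut = p_cut,
                          fdr_cut = fdr_cut, min_normals = min_normals)
    tumor_study <- subset_study(study, samples = which(is_tumor))
    split <- survival_group_split(tumor_study, markers)
    surv <- if (length(unique(split$group)) == 2) km_logrank(split) else NULL

    net <- build_diffcoexp_network(study, p_cut = p_cut,
                                   fdr_cut = fdr_cut,
                                   max_genes = network_max_genes)
    de_genes <- de$gene[de$is_de]
    pairs <- expand.grid(source = intersect(markers, net$nodes),
                         target = intersect(de_genes, net$nodes),
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
    if (nrow(pairs) > max_path_pairs) {
      pairs <- pairs[seq_len(max_path_pairs), , drop = FALSE]
    }
    paths <- shortest_paths_for_pairs(net, pairs)
    enr <- if (length(gene_sets) > 0 && length(paths$paths) > 0) {
      enrich_gene_lists(lapply(paths$paths, identity), gene_sets,
                        universe = rownames(study$matrix),
                        p_cut = p_cut, fdr_cut = fdr_cut)
    } else NULL

    lp <- if (is.null(surv)) NA_real_ else surv$test$p_value
    results[[nm]] <- list(de = de, split = split, survival = surv,
                          network = net, paths = paths, enrichment = enr)
    summary_rows[[nm]] <- data.frame(
      cancer = nm, n_de = sum(de$is_de), logrank_p = lp,
      significant = !is.na(lp) && lp < p_cut, excluded = FALSE,
      reason = "")
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}
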