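#' Summarize probes into gene symbols
#'
#' Collapses a probe x sample matrix to one row per gene symbol by
#' averaging the rows of all probes mapped to that symbol. Probes absent
#' from the mapping are dropped and counted.
#'
#' @param probe_matrix Numeric matrix, probes in rows.
#' @param probe_to_gene Named character vector: names are probe ids,
#'   values gene symbols.
#' @return List with `matrix` (gene x sample) and `n_dropped` (unmapped
#'   probe count).
#' @export
summarize_probes <- function(probe_matrix, probe_to_gene) {
  stopifnot(is.matrix(probe_matrix), !is.null(rownames(probe_matrix)))
  if (length(probe_to_gene) == 0) stop("empty probe-to-gene mapping")
  genes <- probe_to_gene[rownames(probe_matrix)]
  mapped <- !is.na(genes) & nzchar(genes)
  n_dropped <- sum(!mapped)
  sub <- probe_matrix[mapped, , drop = FALSE]
  out <- rowsum(sub, group = genes[mapped]) /
    as.vector(table(genes[mapped])[sort(unique(genes[mapped]))])
  out <- out[order(rownames(out)), , drop = FALSE]
  list(matrix = out, n_dropped = n_dropped)
}

#' Remove genes with too many missing values, zero-fill the rest
#'
#' Genes whose missing fraction is greater than or equal to
#' `max_missing_fraction` (inclusive boundary) are deleted; remaining
#' missing entries are then filled with 0.
#'
#' @param matrix Numeric matrix with `NA` marking missing values.
#' @param max_missing_fraction Deletion threshold in (0, 1], default 0.30.
#' @return Filtered, zero-filled matrix.
#' @export
filter_missing_genes <- function(matrix, max_missing_fraction = 0.30) {
  if (max_missing_fraction <= 0 || max_missing_fraction > 1) {
    stop("config error: max_missing_fraction must lie in (0, 1]")
  }
  frac <- rowMeans(is.na(matrix))
  keep <- frac < max_missing_fraction
  out <- matrix[keep, , drop = FALSE]
  out[is.na(out)] <- 0
  out
}

#' Log-transform a cohort's matrix when it holds linear-scale values
#'
#' Per cohort, if the maximum value exceeds `trigger` the whole cohort
#' block is replaced by log2(x + 1); otherwise it is left untouched. The
#' trigger separates linear-scale microarray/RNAseq values from data that
#' is already on a log scale.
#'
#' @param matrix Numeric gene x sample matrix.
#' @param cohorts Character vector of per-sample cohort ids (default: one
#'   cohort).
#' @param trigger Maximum value above which the transform fires
#'   (default 50).
#' @return List with `matrix` and `transformed` (named logical per cohort).
#' @export
conditional_log_transform <- function(matrix, cohorts = NULL, trigger = 50) {
  if (is.null(cohorts)) cohorts <- rep("all", ncol(matrix))
  stopifnot(length(cohorts) == ncol(matrix))
  transformed <- logical(0)
  for (co in unique(cohorts)) {
    idx <- cohorts == co
    block <- matrix[, idx, drop = FALSE]
    fire <- max(block, na.rm = TRUE) > trigger
    if (fire) {
      if (min(block, na.rm = TRUE) < 0) {
        stop("cohort '", co, "' triggers the log transform but contains ",
             "negative values")
      }
      matrix[, idx] <- log2(block + 1)
    }
    transformed[co] <- fire
  }
  list(matrix = matrix, transformed = transformed)
}

#' Z-score all samples against the control samples
#'
#' Each gene row is transformed as (x - mean_ctrl) / sd_ctrl using the
#' mean and standard deviation over the control columns only, so control
#' columns end up with per-gene mean 0 and sd 1. Genes constant across
#' controls are dropped with a warning.
#'
#' @param matrix Numeric gene x sample matrix.
#' @param control_ids Character vector of control sample column names
#'   (>= 2).
#' @return Normalized matrix (possibly fewer rows).
#' @export
normalize_to_controls <- function(matrix, control_ids) {
  control_ids <- intersect(control_ids, colnames(matrix))
  if (length(control_ids) < 2) stop("need at least 2 control samples")
  ctrl <- matrix[, control_ids, drop = FALSE]
  mu <- rowMeans(ctrl)
  sdv <- apply(ctrl, 1, stats::sd)
  drop <- sdv == 0
  if (any(drop)) {
    warning(sum(drop), " gene(s) constant across controls dropped")
    matrix <- matrix[!drop, , drop = FALSE]
    mu <- mu[!drop]
    sdv <- sdv[!drop]
  }
  (matrix - mu) / sdv
}

#' Remove the top control-sample SVD components from all samples
#'
#' Computes the top `n_components` left-singular (gene-space) vectors of
#' the control submatrix, projects every sample off that subspace, and
#' re-applies control-referenced z-scoring so the corrected controls are
#' again mean 0 / sd 1 per gene. This strips dominant inter-sample
#' variation shared by the controls (batch-like structure) while keeping
#' condition-specific signal.
#'
#' @param matrix Numeric gene x sample matrix (already control z-scored).
#' @param control_ids Control sample column names
#'   (>= n_components + 1).
#' @param n_components Number of components to remove (default 3).
#' @param rescore Re-apply control z-scoring after the projection
#'   (default TRUE; FALSE returns the raw projection, mainly for
#'   inspection).
#' @return Corrected, re-scored matrix.
#' @export
svd_control_correction <- function(matrix, control_ids, n_components = 3,
                                   rescore = TRUE) {
  control_ids <- intersect(control_ids, colnames(matrix))
  if (n_components == 0) {
    if (!rescore) return(matrix)
    return(normalize_to_controls(matrix, control_ids))
  }
  if (length(control_ids) < n_components + 1) {
    stop("need at least n_components + 1 = ", n_components + 1,
         " control samples")
  }
  ctrl <- matrix[, control_ids, drop = FALSE]
  sv <- svd(ctrl, nu = min(n_components, min(dim(ctrl))), nv = 0)
  achievable <- sum(sv$d > 1e-12)
  if (achievable < n_components) {
    stop("control submatrix has rank ", achievable,
         " < n_components = ", n_components)
  }
  u <- sv$u[, seq_len(n_components), drop = FALSE]
  corrected <- matrix - u %*% (t(u) %*% matrix)
  if (!rescore) return(corrected)
  normalize_to_controls(corrected, control_ids)
}

#' Stratified train/test split
#'
#' Splits samples within each of the four age-class x phenotype subgroups
#' independently: round(fraction x subgroup size) samples go to train, the
#' rest to test. Subgroups smaller than 2 are assigned wholly to train
#' with a warning. Deterministic given `seed`.
#'
#' @param samples Metadata data.frame with `age` and `phenotype`.
#' @param train_fraction Fraction in (0, 1), default 2/3.
#' @param seed Integer seed.
#' @param age_cut Aged/young boundary: age > `age_cut` is aged
#'   (default 50).
#' @return Character vector of "train"/"test" labels, one per sample.
#' @export
stratified_split <- function(samples, train_fraction = 2 / 3, seed = 1L,
                             age_cut = 50) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  set.seed(seed)
  aged <- ifelse(samples$age > age_cut, "aged", "young")
  strata <- paste(aged, samples$phenotype, sep = ".")
  split <- rep("test", nrow(samples))
  for (st in unique(strata)) {
    idx <- which(strata == st)
    if (length(idx) < 2) {
      warning("subgroup '", st, "' has fewer than 2 samples; all to train")
      split[idx] <- "train"
      next
    }
    n_train <- round(train_fraction * length(idx))
    split[sample(idx, n_train)] <- "train"
  }
  split
}

#' Run the full preprocessing chain on an expression study
#'
#' Applies, in order: missingness filtering with zero fill, the
#' conditional per-cohort log transform, control-referenced z-scoring,
#' SVD control-component removal with re-scoring, and the stratified
#' train/test split.
#'
#' @param study An [expression_study()].
#' @param max_missing_fraction,n_components,train_fraction,seed,age_cut
#'   Passed to the respective steps.
#' @return A new `expression_study` with normalized matrix and `split`
#'   filled in.
#' @export
preprocess_study <- function(study, max_missing_fraction = 0.30,
                             n_components = 3, train_fraction = 2 / 3,
                             seed = 1L, age_cut = 50) {
  mat <- filter_missing_genes(study$matrix, max_missing_fraction)
  mat <- conditional_log_transform(mat, study$samples$cohort)$matrix
  ctrl_ids <- study$samples$sample_id[study$samples$phenotype == "control"]
  mat <- normalize_to_controls(mat, ctrl_ids)
  mat <- svd_control_correction(mat, ctrl_ids, n_components)
  samples <- study$samples
  samples$split <- stratified_split(samples, train_fraction, seed, age_cut)
  expression_study(mat, samples)
}
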