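#' ReliefF feature ranking
#'
#' Deterministic multi-restart ReliefF: every sample is used as an anchor
#' (no stochastic subsampling), with `n_neighbors` nearest hits and misses
#' per anchor found by Manhattan distance over range-normalized features.
#' A feature's weight accumulates the mean normalized difference to the
#' misses minus that to the hits; informative features therefore get
#' positive weights and constant features exactly 0.
#'
#' @param matrix Numeric feature x sample matrix with rownames.
#' @param labels Binary label vector (two classes, each with >= 2
#'   samples).
#' @param n_neighbors Neighbors per class per anchor (default 10; capped
#'   at class size - 1).
#' @return A `ranked_markers` list: `genes` (ordered by weight descending,
#'   ties broken by symbol), `weights` (same order), `selected_n` (NA
#'   until chosen by cross-validation).
#' @export
relieff_rank <- function(matrix, labels, n_neighbors = 10) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2) stop("labels must contain exactly 2 classes")
  if (min(table(labels)) < 2) stop("each class needs >= 2 samples")

  n <- ncol(matrix)
  rng <- apply(matrix, 1, function(r) diff(range(r)))
  informative <- rng > 0
  xn <- matrix[informative, , drop = FALSE] / rng[informative]

  d <- as.matrix(stats::dist(t(xn), method = "manhattan"))
  w <- numeric(sum(informative))
  for (i in seq_len(n)) {
    same <- which(labels == labels[i] & seq_len(n) != i)
    diff_cl <- which(labels != labels[i])
    k_hit <- min(n_neighbors, length(same))
    k_miss <- min(n_neighbors, length(diff_cl))
    hits <- same[order(d[i, same])[seq_len(k_hit)]]
    misses <- diff_cl[order(d[i, diff_cl])[seq_len(k_miss)]]
    hit_diff <- rowMeans(abs(xn[, hits, drop = FALSE] - xn[, i]))
    miss_diff <- rowMeans(abs(xn[, misses, drop = FALSE] - xn[, i]))
    w <- w + (miss_diff - hit_diff)
  }
  weights <- numeric(nrow(matrix))
  names(weights) <- rownames(matrix)
  weights[informative] <- w / n

  ord <- order(-weights, names(weights))
  structure(list(genes = names(weights)[ord],
                 weights = unname(weights[ord]),
                 selected_n = NA_integer_),
            class = "ranked_markers")
}

#' @export
print.ranked_markers <- function(x, ...) {
  cat(sprintf("ranked_markers: %d genes, selected_n = %s\n",
              length(x$genes), x$selected_n))
  cat("  top:", paste(utils::head(x$genes, 5), collapse = ", "), "\n")
  invisible(x)
}

# 1 - Pearson r between every training and query column over the rows of
# the two matrices; constant vectors get the maximum distance 2.
.cor_dist <- function(train_matrix, query_matrix) {
  r <- suppressWarnings(stats::cor(train_matrix, query_matrix))
  r[is.na(r)] <- -1
  1 - r
}

#' k-nearest-neighbour classification with correlation distance
#'
#' Distance between two samples is 1 - Pearson r over the selected
#' features. The predicted label is the majority among the k nearest
#' training samples; the score is the fraction of those neighbors with
#' label 1. Ties in distance are broken by training-sample order; a label
#' tie (possible for even k) is broken toward the label of the single
#' nearest neighbor. A constant feature vector has undefined correlation
#' and is assigned the maximum distance 2.
#'
#' @param train_matrix Feature x training-sample matrix. Correlation
#'   distance needs >= 2 features; a single-feature model falls back to
#'   absolute difference.
#' @param train_labels Binary labels (0/1) for the training columns.
#' @param query_matrix Feature x query-sample matrix, same feature order.
#' @param k Neighbor count (default 3).
#' @return Data frame with one row per query: `label` (0/1) and `score`
#'   in `[0, 1]`.
#' @export
knn_classify <- function(train_matrix, train_labels, query_matrix, k = 3) {
  stopifnot(nrow(train_matrix) >= 1,
            nrow(train_matrix) == nrow(query_matrix))
  if (k > ncol(train_matrix)) stop("k exceeds the number of training samples")
  train_labels <- as.integer(train_labels)
  d <- if (nrow(train_matrix) == 1) {
    abs(outer(train_matrix[1, ], query_matrix[1, ], "-"))
  } else {
    .cor_dist(train_matrix, query_matrix)
  }
  res <- apply(d, 2, function(dv) {
    nn <- order(dv)[seq_len(k)]
    score <- mean(train_labels[nn])
    label <- if (score > 0.5) 1L else if (score < 0.5) 0L else
      train_labels[nn[1]]
    c(label, score)
  })
  data.frame(label = as.integer(res[1, ]), score = res[2, ],
             row.names = NULL)
}

# Stratified fold assignment, deterministic in seed.
.stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Learning curve over nested top-m feature sets with CV model selection
#'
#' For m = 1 ... `max_features`, computes the mean stratified
#' `folds`-fold cross-validated accuracy of correlation-distance kNN on
#' the top-m ranked features, and selects the smallest m attaining the
#' maximum. Correlations over nested feature prefixes are computed from
#' cumulative sums, so the full curve costs little more than the largest
#' model.
#'
#' @param matrix Feature x sample matrix (training data).
#' @param labels Binary labels (0/1).
#' @param ranked A `ranked_markers` object from [relieff_rank()].
#' @param max_features Largest model size scanned (default 500).
#' @param folds CV folds (default 10; must not exceed the smaller class).
#' @param k kNN neighbor count (default 3).
#' @param seed Seed for the fold assignment.
#' @return List: `curve` (accuracy per m), `selected_n`, `folds`, `k`.
#' @export
learning_curve_select <- function(matrix, labels, ranked,
                                  max_features = 500, folds = 10, k = 3,
                                  seed = 1L) {
  labels <- as.integer(labels)
  max_features <- min(max_features, length(ranked$genes), nrow(matrix))
  if (folds > min(table(labels))) {
    stop("folds = ", folds, " exceeds the smaller class size (",
         min(table(labels)), ")")
  }
  genes <- ranked$genes[seq_len(max_features)]
  x <- matrix[genes, , drop = FALSE]
  fold <- .stratified_folds(labels, folds, seed)

  acc <- matrix(NA_real_, nrow = max_features, ncol = folds)
  for (f in seq_len(folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    if (length(te) == 0) next
    correct <- .prefix_knn_correct(x[, tr, drop = FALSE], labels[tr],
                                   x[, te, drop = FALSE], labels[te], k)
    acc[, f] <- correct / length(te)
  }
  curve <- rowMeans(acc, na.rm = TRUE)
  selected_n <- which.max(curve)  # which.max returns the smallest argmax
  list(curve = curve, selected_n = as.integer(selected_n),
       folds = folds, k = k)
}

# For every feature-prefix length m, counts correct kNN predictions of the
# test columns. Prefix correlations come from cumulative sums:
# r_m = (m*Sxy - Sx*Sy) / sqrt((m*Sxx - Sx^2)(m*Syy - Sy^2)).
.prefix_knn_correct <- function(xtr, ytr, xte, yte, k) {
  m_max <- nrow(xtr)
  n_tr <- ncol(xtr)
  cs_tr <- apply(xtr, 2, cumsum)
  cs_tr2 <- apply(xtr^2, 2, cumsum)
  cs_te <- apply(xte, 2, cumsum)
  cs_te2 <- apply(xte^2, 2, cumsum)
  m_vec <- seq_len(m_max)
  var_tr <- m_vec * cs_tr2 - cs_tr^2          # m_max x n_tr
  correct <- numeric(m_max)
  for (v in seq_len(ncol(xte))) {
    cs_xy <- apply(xtr * xte[, v], 2, cumsum)  # m_max x n_tr
    num <- m_vec * cs_xy - cs_tr * cs_te[, v]
    var_te <- m_vec * cs_te2[, v] - cs_te[, v]^2
    denom <- sqrt(pmax(var_tr, 0) * pmax(var_te, 0))
    r <- num / denom
    r[!is.finite(r)] <- -1                     # constant prefix -> distance 2
    for (m in seq_len(m_max)) {
      if (m == 1) {
        # single feature: |r| = 1 everywhere; fall back to absolute
        # difference so the 1-feature model is still meaningful
        dv <- abs(xtr[1, ] - xte[1, v])
      } else {
        dv <- 1 - r[m, ]
      }
      kk <- min(k, n_tr)
      nn <- order(dv)[seq_len(kk)]
      score <- mean(ytr[nn])
      pred <- if (score > 0.5) 1L else if (score < 0.5) 0L else ytr[nn[1]]
      if (pred == yte[v]) correct[m] <- correct[m] + 1
    }
  }
  correct
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, with ties counted one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train an aging or disease predictor on a preprocessed study
#'
#' Builds the task's labels (aging: healthy aged = 1 vs healthy young = 0;
#' disease: T2DM = 1 vs young controls = 0), ranks genes by ReliefF on the
#' training split, selects the model size by the cross-validated learning
#' curve, and evaluates on the held-out test split.
#'
#' @param study A preprocessed [expression_study()] with `split` assigned.
#' @param task `"aging"` or `"disease"`.
#' @param max_features,folds,k,n_neighbors,seed Tuning parameters, see
#'   [learning_curve_select()] and [relieff_rank()].
#' @param age_cut Aged/young boundary in years (default 50).
#' @param include_aged_controls For the disease task, whether aged
#'   controls join the control class (default FALSE: young controls only).
#' @return List: `ranked` (with `selected_n` filled), `markers` (the
#'   selected gene symbols), `eval` (curve, train/test accuracy, AUC,
#'   per-sample predictions).
#' @export
train_predictor <- function(study, task = c("aging", "disease"),
                            max_features = 500, folds = 10, k = 3,
                            n_neighbors = 10, seed = 1L, age_cut = 50,
                            include_aged_controls = FALSE) {
  task <- match.arg(task)
  meta <- study$samples
  aged <- meta$age > age_cut
  if (task == "aging") {
    use <- meta$phenotype == "control"
    label <- as.integer(aged)
  } else {
    use <- meta$phenotype == "T2DM" |
      (meta$phenotype == "control" & (include_aged_controls | !aged))
    label <- as.integer(meta$phenotype == "T2DM")
  }
  tr <- use & meta$split == "train"
  te <- use & meta$split == "test"
  xtr <- study$matrix[, tr, drop = FALSE]
  xte <- study$matrix[, te, drop = FALSE]
  ytr <- label[tr]
  yte <- label[te]

  ranked <- relieff_rank(xtr, ytr, n_neighbors = n_neighbors)
  sel <- learning_curve_select(xtr, ytr, ranked, max_features = max_features,
                               folds = folds, k = k, seed = seed)
  ranked$selected_n <- sel$selected_n
  markers <- ranked$genes[seq_len(sel$selected_n)]

  pred_tr <- knn_classify(xtr[markers, , drop = FALSE], ytr,
                          xtr[markers, , drop = FALSE], k = k)
  pred_te <- knn_classify(xtr[markers, , drop = FALSE], ytr,
                          xte[markers, , drop = FALSE], k = k)
  eval <- list(
    cv_accuracy_curve = sel$curve,
    train_accuracy = mean(pred_tr$label == ytr),
    test_accuracy = mean(pred_te$label == yte),
    auc = roc_auc(pred_te$score, yte),
    predictions = data.frame(sample_id = meta$sample_id[te],
                             truth = yte, label = pred_te$label,
                             score = pred_te$score)
  )
  list(task = task, ranked = ranked, markers = markers, eval = eval)
}
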