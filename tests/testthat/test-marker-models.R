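test_that("ReliefF ranks an informative feature first and zeroes constants", {
  set.seed(31)
  n <- 40
  y <- rep(0:1, each = n / 2)
  m <- matrix(rnorm(20 * n), 20, n,
              dimnames = list(sprintf("noise%02d", 1:20), NULL))
  m <- rbind(m, signal = y + rnorm(n, sd = 0.05),
             flatline = rep(2, n))
  colnames(m) <- sprintf("s%02d", 1:n)
  rk <- relieff_rank(m, y)
  expect_equal(rk$genes[1], "signal")
  expect_equal(rk$weights[match("flatline", rk$genes)], 0)
  expect_true(!is.unsorted(rev(rk$weights)))
  signal_w <- rk$weights[1]

  # label permutation: no feature should approach the informative weight
  set.seed(32)
  perm_max <- replicate(5, {
    rp <- relieff_rank(m[rownames(m) != "signal", , drop = FALSE],
                       sample(y))
    max(abs(rp$weights))
  })
  expect_true(all(perm_max < signal_w))

  expect_error(relieff_rank(m, rep(1, n)), "2 classes")
})

test_that("correlation-distance kNN matches the exhaustive oracle", {
  set.seed(41)
  train <- matrix(rnorm(5 * 12), 5, 12)
  labels <- rep(0:1, 6)
  query <- matrix(rnorm(5 * 6), 5, 6)
  for (k in c(1, 3, 5)) {
    got <- knn_classify(train, labels, query, k = k)
    for (j in 1:6) {
      ora <- oracle_knn(train, labels, query[, j], k)
      expect_equal(got$label[j], ora$label)
      expect_equal(got$score[j], ora$score)
    }
  }
})

test_that("kNN respects correlation-distance geometry", {
  set.seed(42)
  train <- matrix(rnorm(6 * 8), 6, 8)
  labels <- c(1, 0, 0, 1, 0, 1, 0, 1)
  # query identical to a training sample, k = 1 -> that sample's label
  got <- knn_classify(train, labels, train[, 3, drop = FALSE], k = 1)
  expect_equal(got$label, 0L)
  expect_equal(got$score, 0)
  # affine transform of a training sample is at distance zero from it
  q <- 2 * train[, 6, drop = FALSE] + 5
  got2 <- knn_classify(train, labels, q, k = 1)
  expect_equal(got2$label, 1L)
  # per-sample affine transforms of all vectors leave predictions unchanged
  q3 <- matrix(rnorm(6 * 4), 6, 4)
  base <- knn_classify(train, labels, q3, k = 3)
  scale_tr <- sweep(sweep(train, 2, runif(8, 0.5, 2), "*"), 2,
                    rnorm(8), "+")
  scale_q <- sweep(sweep(q3, 2, runif(4, 0.5, 2), "*"), 2, rnorm(4), "+")
  expect_equal(knn_classify(scale_tr, labels, scale_q, k = 3), base)
  # constant query vector: maximum distance, still classifies
  cq <- matrix(1, 6, 1)
  expect_silent(knn_classify(train, labels, cq, k = 3))
  expect_error(knn_classify(train, labels, q3, k = 9), "exceeds")
})

test_that("learning curve selection agrees with direct kNN and picks ties small", {
  set.seed(51)
  n <- 36
  y <- rep(0:1, each = n / 2)
  m <- matrix(rnorm(30 * n), 30, n,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%02d", 1:n)))
  m["f01", ] <- y * 10 + rnorm(n, sd = 0.01)  # perfectly separating
  rk <- relieff_rank(m, y)
  expect_equal(rk$genes[1], "f01")
  sel <- learning_curve_select(m, y, rk, max_features = 30, folds = 4,
                               seed = 2)
  expect_equal(sel$curve[1], 1)
  expect_equal(sel$selected_n, 1L)

  # prefix-sum correlation path equals knn_classify fold by fold
  fold <- oxaging:::.stratified_folds(y, 4, 2)
  for (m_try in c(3, 11, 30)) {
    acc <- numeric(4)
    for (f in 1:4) {
      tr <- fold != f
      pr <- knn_classify(m[rk$genes[1:m_try], tr, drop = FALSE], y[tr],
                         m[rk$genes[1:m_try], !tr, drop = FALSE], k = 3)
      acc[f] <- mean(pr$label == y[!tr])
    }
    expect_equal(sel$curve[m_try], mean(acc), tolerance = 1e-12)
  }
  expect_error(learning_curve_select(m, y, rk, folds = 20), "class size")
})

test_that("roc_auc equals pairwise counting with half-credit ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  set.seed(61)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    expect_equal(roc_auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(0.3, 0.4), c(1, 1)), "both classes")
})

test_that("predictors beat chance on planted signal and not on permuted labels", {
  cfg <- cohort_config(n_genes = 400, n_per_subgroup = c(30, 20, 20, 10),
                       n_true_triples = 8, n_signflip_pairs = 0, seed = 71)
  sim <- generate_cohort(cfg)
  study <- preprocess_study(sim$study, seed = 3)
  dis <- train_predictor(study, "disease", max_features = 100, seed = 4)
  expect_gt(dis$eval$test_accuracy, 0.6)
  expect_gt(dis$eval$auc, 0.6)
  expect_true(all(dis$eval$cv_accuracy_curve >= 0 &
                    dis$eval$cv_accuracy_curve <= 1))
  expect_lte(dis$ranked$selected_n, 100)

  # aging signal lives in the aged-vs-young control contrast, which the
  # SVD control correction partly absorbs; score it without that step
  study_nosvd <- preprocess_study(sim$study, n_components = 0, seed = 3)
  aging <- train_predictor(study_nosvd, "aging", max_features = 100,
                           seed = 4)
  expect_gt(aging$eval$auc, 0.6)

  # permuted labels: accuracy near chance
  perm <- study
  set.seed(5)
  t2 <- perm$samples$phenotype
  perm$samples$phenotype <- sample(t2)
  dp <- train_predictor(perm, "disease", max_features = 100, seed = 4)
  expect_lt(dp$eval$test_accuracy, 0.78)
})
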