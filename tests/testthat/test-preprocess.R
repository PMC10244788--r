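test_that("probe summarization averages rows per gene and counts drops", {
  pm <- matrix(c(1, 3, 3, 5, 7, 9), nrow = 3, byrow = TRUE,
               dimnames = list(c("P1", "P2", "P3"), c("s1", "s2")))
  map <- c(P1 = "GENE1", P2 = "GENE1")
  out <- summarize_probes(pm, map)
  expect_equal(out$matrix["GENE1", ], c(s1 = 2, s2 = 4))
  expect_equal(out$n_dropped, 1)
  expect_equal(nrow(out$matrix), 1)

  map2 <- c(P1 = "A", P2 = "B", P3 = "C")
  out2 <- summarize_probes(pm, map2)
  expect_equal(out2$n_dropped, 0)
  expect_equal(unname(out2$matrix[c("A", "B", "C"), ]), unname(pm))
  expect_error(summarize_probes(pm, character(0)), "empty")
})

test_that("missingness filter uses an inclusive 30% boundary then zero-fills", {
  m <- matrix(rnorm(30), nrow = 3,
              dimnames = list(c("g30", "g20", "g0"), NULL))
  m["g30", 1:3] <- NA  # exactly 30% -> deleted
  m["g20", 1:2] <- NA  # 20% -> kept, zero-filled
  out <- filter_missing_genes(m, 0.30)
  expect_equal(rownames(out), c("g20", "g0"))
  expect_equal(out["g20", 1:2], c(0, 0))
  expect_false(anyNA(out))
  full <- matrix(1:12, 3)
  rownames(full) <- letters[1:3]
  expect_equal(filter_missing_genes(full), full)
  expect_error(filter_missing_genes(m, 0), "config")
})

test_that("log transform fires per cohort above the trigger", {
  m <- matrix(c(12.3, 5, 1023, 40), nrow = 1)
  colnames(m) <- paste0("s", 1:4)
  rownames(m) <- "g1"
  out <- conditional_log_transform(m, cohorts = c("a", "a", "b", "b"))
  expect_false(out$transformed[["a"]])
  expect_true(out$transformed[["b"]])
  expect_equal(out$matrix[1, 1:2], c(s1 = 12.3, s2 = 5))
  expect_equal(unname(out$matrix[1, 3]), 10)  # log2(1024)

  z <- matrix(0, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_equal(conditional_log_transform(z)$matrix, z)

  neg <- matrix(c(-1, 100), nrow = 1,
                dimnames = list("g", c("s1", "s2")))
  expect_error(conditional_log_transform(neg), "negative")
})

test_that("control-referenced z-scoring hits the closed form and idempotence", {
  m <- matrix(c(1, 3, 5), nrow = 1,
              dimnames = list("g1", c("c1", "c2", "t1")))
  out <- normalize_to_controls(m, c("c1", "c2"))
  expect_equal(unname(out[1, ]), c(-1, 1, 3) / sqrt(2), tolerance = 1e-12)

  set.seed(2)
  m2 <- matrix(rnorm(50), 5, 10,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  n1 <- normalize_to_controls(m2, paste0("s", 1:6))
  n2 <- normalize_to_controls(n1, paste0("s", 1:6))
  expect_equal(n1, n2, tolerance = 1e-12)
  expect_equal(unname(rowMeans(n1[, 1:6])), rep(0, 5), tolerance = 1e-12)

  m2["g3", 1:6] <- 7
  expect_warning(out3 <- normalize_to_controls(m2, paste0("s", 1:6)),
                 "constant")
  expect_false("g3" %in% rownames(out3))
  expect_error(normalize_to_controls(m2, "s1"), "2 control")
})

test_that("SVD correction projects controls off their top components", {
  set.seed(4)
  # control variation spanned by exactly 3 gene-space directions
  u <- qr.Q(qr(matrix(rnorm(20 * 3), 20)))
  ctrl <- u %*% matrix(rnorm(3 * 8, sd = 2), 3)
  t2dm <- matrix(rnorm(20 * 7), 20)
  m <- cbind(ctrl, t2dm)
  dimnames(m) <- list(paste0("g", 1:20), paste0("s", 1:15))
  raw <- svd_control_correction(m, paste0("s", 1:8), 3, rescore = FALSE)
  expect_lt(max(abs(raw[, 1:8])), 1e-8)

  # orthogonality of the projection on a generic fixture
  m2 <- matrix(rnorm(20 * 15), 20,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:15)))
  corr <- svd_control_correction(m2, paste0("s", 1:8), 3, rescore = FALSE)
  sv <- svd(m2[, 1:8], nu = 3, nv = 0)
  expect_lt(max(abs(t(sv$u) %*% corr[, 1:8])), 1e-8)

  expect_equal(svd_control_correction(m2, paste0("s", 1:8), 0,
                                      rescore = FALSE), m2)
  expect_error(svd_control_correction(m2, paste0("s", 1:2), 3),
               "control")
  rank2 <- m2
  rank2[, 1:8] <- m2[, 1:2] %*% matrix(1, 2, 8)
  expect_error(svd_control_correction(rank2, paste0("s", 1:8), 5),
               "rank")
})

test_that("stratified split reproduces subgroup-wise counts deterministically", {
  meta <- data.frame(sample_id = sprintf("x%03d", 1:208),
                     age = rep(60, 208), phenotype = "control")
  s <- stratified_split(meta, train_fraction = 145 / 208, seed = 3)
  expect_equal(sum(s == "train"), 145)
  expect_equal(sum(s == "test"), 63)

  meta2 <- data.frame(sample_id = sprintf("y%02d", 1:90),
                      age = rep(30, 90), phenotype = "T2DM")
  s2 <- stratified_split(meta2, 2 / 3, seed = 8)
  expect_equal(sum(s2 == "train"), 60)
  expect_identical(s2, stratified_split(meta2, 2 / 3, seed = 8))
  expect_false(identical(s2, stratified_split(meta2, 2 / 3, seed = 9)))

  # stratification: counts hold within each subgroup
  cfg <- cohort_config(n_genes = 20, n_per_subgroup = c(12, 9, 9, 6),
                       n_true_triples = 0, n_signflip_pairs = 0, seed = 2)
  sim <- generate_cohort(cfg)
  sp <- stratified_split(sim$study$samples, 2 / 3, seed = 5)
  meta3 <- sim$study$samples
  strata <- paste(meta3$age > 50, meta3$phenotype)
  for (st in unique(strata)) {
    idx <- strata == st
    expect_equal(sum(sp[idx] == "train"), round(2 / 3 * sum(idx)))
  }
  expect_error(stratified_split(meta2, 1.5), "between 0 and 1")
})

test_that("the preprocessing chain preserves sample order and only drops genes", {
  cfg <- cohort_config(n_genes = 120, n_per_subgroup = c(10, 8, 8, 6),
                       n_true_triples = 3, n_signflip_pairs = 2, seed = 12)
  sim <- generate_cohort(cfg)
  out <- preprocess_study(sim$study, seed = 4)
  expect_identical(colnames(out$matrix), colnames(sim$study$matrix))
  expect_true(all(rownames(out$matrix) %in% rownames(sim$study$matrix)))
  expect_true(all(out$samples$split %in% c("train", "test")))
  ctrl <- out$samples$phenotype == "control"
  expect_lt(max(abs(rowMeans(out$matrix[, ctrl]))), 1e-10)
})
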