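test_that("tumor/normal DE applies the three criteria with direction symmetry", {
  cfg <- cohort_config(n_genes = 200, noise_sd = 0.25, seed = 151,
                       n_true_triples = 0, n_signflip_pairs = 0)
  pc <- generate_pancancer_cohort(cfg, n_tumor = 40, n_normal = 40,
                                  n_de = 25, de_fold = 4)
  is_t <- pc$study$samples$phenotype == "tumor"
  de <- tumor_normal_de(pc$study$matrix[, is_t],
                        pc$study$matrix[, !is_t])
  found <- de$gene[de$is_de]
  expect_gte(length(intersect(found, pc$truth$de_genes)), 22)
  expect_lte(length(setdiff(found, pc$truth$de_genes)), 3)
  expect_true(all(de$is_de == ((de$fold_change > 2 |
                                  de$fold_change < 0.5) &
                                 de$p < 0.05 & de$fdr < 0.1)))

  # swapping tumor and normal inverts fold changes, keeps calls
  swap <- tumor_normal_de(pc$study$matrix[, !is_t],
                          pc$study$matrix[, is_t],
                          min_normals = 10)
  expect_equal(swap$fold_change, 1 / de$fold_change, tolerance = 1e-6)
  expect_equal(swap$is_de, de$is_de)

  expect_error(tumor_normal_de(pc$study$matrix[, is_t],
                               pc$study$matrix[, 1:9]), "excluded")
})

test_that("duplicate patient profiles are averaged by patient id", {
  m <- matrix(c(1, 3, 10, 2, 4, 10), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("p1a", "p1b", "p2")))
  out <- average_duplicate_patients(m, c("p1", "p1", "p2"))
  expect_equal(out[, "p1"], c(g1 = 2, g2 = 3))
  expect_equal(out[, "p2"], c(g1 = 10, g2 = 10))
})

test_that("survival splitting uses the mean score rule", {
  m <- matrix(c(1, 3, 2, 0, 2, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  meta <- data.frame(sample_id = c("s1", "s2", "s3"), age = NA,
                     phenotype = "tumor", time = c(10, 20, 30),
                     event = c(1, 0, 1))
  st <- expression_study(m, meta)
  sc <- survival_group_split(st, c("g1", "g2"))
  expect_equal(sc$score, c(0.5, 2.5, 3))  # means over markers
  expect_equal(sc$group, c("low", "high", "high"))
  # single marker: score is that gene's value
  sc1 <- survival_group_split(st, "g1")
  expect_equal(sc1$score, unname(m["g1", ]))
  expect_error(survival_group_split(st, "absent"), "marker")
  m0 <- m * 0
  st0 <- expression_study(m0, meta)
  expect_warning(survival_group_split(st0, "g1"), "degenerate")
})

test_that("log-rank agrees with hand tabulation and identical groups are null", {
  coh <- data.frame(sample_id = letters[1:6],
                    time = c(1, 2, 3, 4, 5, 6), event = 1,
                    group = rep(c("A", "B"), each = 3))
  got <- km_logrank(coh)
  ora <- oracle_logrank(coh$time, coh$event, coh$group)
  expect_equal(got$test$statistic, unname(ora["chisq"]), tolerance = 1e-8)
  expect_equal(got$test$p_value, unname(ora["p"]), tolerance = 1e-8)
  expect_true(all(c("group", "time", "survival") %in% names(got$curves)))

  same <- data.frame(sample_id = letters[1:8],
                     time = rep(c(2, 4, 6, 8), 2),
                     event = rep(c(1, 0, 1, 1), 2),
                     group = rep(c("A", "B"), each = 4))
  got2 <- km_logrank(same)
  expect_equal(got2$test$statistic, 0, tolerance = 1e-10)
  expect_equal(got2$test$p_value, 1, tolerance = 1e-10)

  ze <- data.frame(sample_id = letters[1:6], time = 1:6,
                   event = c(1, 1, 1, 0, 0, 0),
                   group = rep(c("A", "B"), each = 3))
  expect_warning(km_logrank(ze), "zero events")
})

test_that("log-rank detects a planted hazard effect in most replicates", {
  hits <- 0
  n_rep <- 25
  for (s in seq_len(n_rep)) {
    cfg <- cohort_config(n_genes = 150, seed = 3000 + s,
                         n_true_triples = 0, n_signflip_pairs = 0)
    pc <- generate_pancancer_cohort(cfg, n_tumor = 100, n_normal = 10,
                                    hazard_beta = log(2))
    tum <- subset_study(pc$study,
                        samples = which(pc$study$samples$phenotype == "tumor"))
    spl <- survival_group_split(tum, pc$truth$survival_markers)
    hits <- hits + (km_logrank(spl)$test$p_value < 0.05)
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("pancancer_run bundles per-cancer results and excludes thin cohorts", {
  cfgA <- cohort_config(n_genes = 150, seed = 161, n_true_triples = 0,
                        n_signflip_pairs = 0)
  cfgB <- cohort_config(n_genes = 150, seed = 162, n_true_triples = 0,
                        n_signflip_pairs = 0)
  a <- generate_pancancer_cohort(cfgA, n_tumor = 50, n_normal = 15,
                                 hazard_beta = log(2))
  b <- generate_pancancer_cohort(cfgB, n_tumor = 30, n_normal = 9)
  sets <- list(PATH_ONE = rownames(a$study$matrix)[1:30])
  out <- pancancer_run(list(CA = a, CB = b),
                       markers = a$truth$survival_markers,
                       gene_sets = sets)
  expect_equal(nrow(out$summary), 2)
  expect_true(out$summary$excluded[out$summary$cancer == "CB"])
  expect_match(out$summary$reason[out$summary$cancer == "CB"], "9 normals")
  ca <- out$results$CA
  expect_true(is.data.frame(ca$de))
  expect_true(!is.null(ca$survival))
  expect_false(out$summary$excluded[out$summary$cancer == "CA"])
  expect_error(pancancer_run(list(), "g"), "empty")

  # determinism of the bundle
  out2 <- pancancer_run(list(CA = a, CB = b),
                        markers = a$truth$survival_markers,
                        gene_sets = sets)
  expect_identical(out$summary, out2$summary)
})
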