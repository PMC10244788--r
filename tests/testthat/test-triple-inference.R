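test_that("GMT keyword selection unions matching sets within the universe", {
  gmt <- tempfile(fileext = ".gmt")
  write_gmt(list(GOBP_OXIDATIVE_X = c("g1", "g2"),
                 GOBP_GLYCOLYSIS = c("g3"),
                 KEGG_oxidative_y = c("g2", "g4", "g9")), gmt)
  uni <- c("g1", "g2", "g3", "g4")
  expect_equal(load_gene_sets_by_keyword(gmt, uni), c("g1", "g2", "g4"))
  expect_warning(res <- load_gene_sets_by_keyword(gmt, uni, "NOMATCH"),
                 "keyword")
  expect_equal(res, character(0))

  bad <- tempfile(fileext = ".gmt")
  writeLines(c("SET1\tdesc\tg1", "SET2_only_name"), bad)
  expect_error(read_gmt(bad), "line 2")
})

test_that("diffcoexp_test is the Kruskal-Wallis test of the sample products", {
  x <- rep(1, 8)
  y <- c(1, 1, 1, 1, 3, 3, 3, 3)
  ph <- rep(c("control", "T2DM"), each = 4)
  got <- diffcoexp_test(x, y, ph)
  ora <- oracle_kw(x * y, ph)
  expect_equal(got$p_value, unname(ora["p"]), tolerance = 1e-12)
  expect_lt(got$p_value, 0.05)
  # constant partner: all products tie
  expect_equal(diffcoexp_test(rnorm(8), rep(0, 8), ph)$p_value, 1)
})

test_that("planted T2DM-only coupling is detected in most replicates", {
  hits <- 0
  n_rep <- 30
  for (s in seq_len(n_rep)) {
    cfg <- cohort_config(n_genes = 30,
                         n_per_subgroup = c(50, 50, 50, 50),
                         n_true_triples = 1, n_signflip_pairs = 0,
                         delta = 0, lambda = 0.9, seed = 500 + s)
    sim <- generate_cohort(cfg)
    tr <- sim$truth$triples[1, ]
    p <- diffcoexp_test(sim$study$matrix[tr$aging, ],
                        sim$study$matrix[tr$oxidative, ],
                        sim$study$samples$phenotype)$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("pair screening excludes self-pairs and controls the null", {
  cfg <- cohort_config(n_genes = 60, n_per_subgroup = c(20, 20, 20, 20),
                       n_true_triples = 0, n_signflip_pairs = 0, seed = 81)
  sim <- generate_cohort(cfg)
  genes <- rownames(sim$study$matrix)
  tab <- screen_marker_pairs(genes[1:20], genes[1:20], sim$study)
  expect_false(any(tab$gene_a == tab$gene_b))
  expect_equal(nrow(tab), 20 * 19)
  expect_lte(sum(tab$retained), 4)  # null data, BH controls retention
  expect_warning(out <- screen_marker_pairs(character(0), genes[1:3],
                                            sim$study), "empty")
  expect_equal(nrow(out), 0)
})

test_that("permutation pair test honors its boundary definitions", {
  cm <- matrix(1, 20, 12,
               dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:12)))
  st <- make_study(cm, rep(c("control", "T2DM"), each = 6))
  expect_equal(permutation_pair_test("g01", "g02", st, n_perm = 100), 1)

  set.seed(91)
  m <- matrix(rnorm(20 * 12, sd = 0.01), 20, 12,
              dimnames = dimnames(cm))
  m["g01", 7:12] <- 100  # huge observed difference, null universe
  st2 <- make_study(m, rep(c("control", "T2DM"), each = 6))
  expect_equal(permutation_pair_test("g01", "g02", st2, n_perm = 200), 0)

  tiny <- make_study(m[1:5, ], rep(c("control", "T2DM"), each = 6))
  expect_error(permutation_pair_test("g01", "g02", tiny), ">= 10")

  # planted coupling stands out against the replacement null
  cfg <- cohort_config(n_genes = 200, n_per_subgroup = c(10, 10, 70, 70),
                       n_true_triples = 1, n_signflip_pairs = 0,
                       delta = 0, seed = 92)
  sim <- generate_cohort(cfg)
  tr <- sim$truth$triples[1, ]
  expect_lt(permutation_pair_test(tr$aging, tr$oxidative, sim$study,
                                  n_perm = 500, seed = 3), 0.05)
})

test_that("confounder screen returns the first qualifying gene or none", {
  scans <- list(
    A = data.frame(gene = c("z1", "z2", "z3"),
                   p = c(0.01, 0.2, 0.001), fdr = c(0.05, 0.5, 0.01)),
    D = data.frame(gene = c("z1", "z2", "z3"),
                   p = c(0.02, 0.01, 0.001), fdr = c(0.08, 0.04, 0.02))
  )
  expect_equal(confounder_screen("A", "D", scans), "z1")
  expect_equal(confounder_screen("A", "D", scans, exclude = "z1"), "z3")
  expect_equal(confounder_screen("A", "D", scans, exclude = c("z1", "z3")),
               NA_character_)
  expect_error(confounder_screen("A", "X", scans), "missing")
})

test_that("pleiotropy regressions produce orthogonal residuals and flag degeneracy", {
  set.seed(95)
  n <- 100
  ph <- rep(c("control", "T2DM"), each = n / 2)
  a <- rnorm(n)
  o <- 0.9 * a + rnorm(n, sd = 0.5)
  d <- 0.9 * o + rnorm(n, sd = 0.5)
  pl <- pleiotropy_screen(a, o, d, ph)
  expect_equal(unname(pl$b["b1"]), coef(lm(d ~ o))[[2]], tolerance = 1e-10)
  expect_equal(unname(pl$b["b2"]), coef(lm(a ~ o))[[2]], tolerance = 1e-10)
  expect_equal(unname(pl$b["b4"]), coef(lm(d ~ a))[[2]], tolerance = 1e-10)
  expect_lt(abs(cov(pl$residuals$A, o)), 1e-10)
  expect_lt(abs(cov(pl$residuals$B, o)), 1e-10)
  expect_lt(abs(cov(pl$residuals$C, pl$residuals$B)), 1e-10)
  expect_lt(abs(cov(pl$residuals$D, a)), 1e-10)
  expect_true(pl$test$p_value >= 0 && pl$test$p_value <= 1)
  expect_error(pleiotropy_screen(a, a, d, ph), "degenerate")
})

test_that("assembled triples recover planted structure with few false hits", {
  # delta = 0 isolates the mediation-recovery mechanics; the default
  # shifted conditions are exercised in the acceptance suite
  cfg <- cohort_config(n_genes = 400, n_per_subgroup = c(20, 15, 35, 30),
                       n_true_triples = 5, n_signflip_pairs = 0,
                       delta = 0, seed = 97)
  sim <- generate_cohort(cfg)
  study <- preprocess_study(sim$study, seed = 3)
  truth <- sim$truth$triples
  set.seed(98)
  decoys <- sample(setdiff(rownames(study$matrix), unlist(truth)), 45)
  res <- assemble_triples(c(truth$aging, decoys[1:15]),
                          c(truth$disease, decoys[16:30]),
                          c(truth$oxidative, decoys[31:45]),
                          study, n_perm = 300, seed = 6)
  tt <- res$triples
  key <- function(d) paste(d$aging, d$oxidative, d$disease)
  ret <- tt[tt$retained, ]
  expect_gte(sum(key(ret) %in% key(truth)), 2)
  expect_lte(sum(!key(ret) %in% key(truth)), 2)

  # filters only remove: retained triples passed every screen stage
  expect_true(all(ret$p_ao < 0.05 & ret$fdr_ao < 0.1))
  expect_true(all(ret$p_od < 0.05 & ret$fdr_od < 0.1))
  expect_true(all(ret$perm_p_ao < 0.05 & ret$perm_p_od < 0.05))
  expect_true(all(is.na(ret$confounder_hit)))
  expect_false(any(ret$aging == ret$oxidative |
                     ret$aging == ret$disease |
                     ret$oxidative == ret$disease))

  # occurrence bookkeeping: per-role counts sum to the retained total
  if (nrow(ret) > 0) {
    expect_equal(sum(res$occurrence$aging), nrow(ret))
    expect_equal(sum(res$occurrence$oxidative), nrow(ret))
    expect_equal(sum(res$occurrence$disease), nrow(ret))
  }
  expect_equal(unname(res$marker_counts["aging"]),
               length(unique(ret$aging)))

  expect_warning(empty <- assemble_triples(character(0), "g1", "g2",
                                           study), "empty")
  expect_equal(nrow(empty$triples), 0)
})
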