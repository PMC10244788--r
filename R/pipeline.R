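#' Build a synthetic gene-set collection around the planted truth
#'
#' Produces a GMT-style list whose "OXIDATIVE" set contains the planted
#' oxidative marker genes (padded with random measured genes) plus decoy
#' sets of random genes, so the keyword-driven candidate selection and
#' the enrichment stage are exercisable on synthetic cohorts.
#'
#' @param truth A `truth_table` from [generate_cohort()].
#' @param universe Measured gene symbols.
#' @param set_size Genes per set (default 40).
#' @param n_decoy_sets Number of non-matching sets (default 10).
#' @param seed Integer seed.
#' @return Named list of gene sets.
#' @export
synthetic_gmt <- function(truth, universe, set_size = 40,
                          n_decoy_sets = 10, seed = 1L) {
  set.seed(seed)
  ox <- intersect(truth$triples$oxidative, universe)
  pad <- sample(setdiff(universe, ox), max(0, set_size - length(ox)))
  sets <- list(GOBP_OXIDATIVE_STRESS_RESPONSE = sort(c(ox, pad)))
  for (i in seq_len(n_decoy_sets)) {
    sets[[sprintf("GOBP_DECOY_SET_%02d", i)]] <-
      sort(sample(universe, set_size))
  }
  sets
}

#' Pipeline configuration
#'
#' Collects every stage's tunable constants in one place. Defaults are
#' the pipeline's canonical thresholds: p < 0.05 with BH FDR < 0.1 at
#' every screen, 1000 permutations, kNN k = 3, disease-score k = 7,
#' learning curve over the top 500 features with 10-fold CV, and 1000
#' accepted MCMC samples per group.
#'
#' @param cohort A [cohort_config()] for the synthetic stage.
#' @param p_cut,fdr_cut,perm_p_cut Screen thresholds.
#' @param n_perm Permutations for pair and betweenness nulls.
#' @param k_knn,k_score,max_features,folds Predictor constants.
#' @param n_accept,burn_in,proposal_scale,beta MCMC constants.
#' @param network_max_genes Gene cap for the all-pairs network.
#' @param run_sensitivity,run_network,run_enrichment,run_pancancer Stage
#'   toggles.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            p_cut = 0.05, fdr_cut = 0.1,
                            perm_p_cut = 0.05, n_perm = 1000,
                            k_knn = 3, k_score = 7, max_features = 500,
                            folds = 10, n_accept = 1000, burn_in = 500,
                            proposal_scale = 0.25, beta = 1.0,
                            network_max_genes = 500,
                            run_sensitivity = TRUE, run_network = TRUE,
                            run_enrichment = TRUE, run_pancancer = FALSE,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> preprocess -> aging/disease predictors ->
#' triple assembly -> MCMC sensitivity -> differential coexpression
#' network with shortest paths and betweenness markers -> enrichment
#' (-> optional pan-cancer stage), writing every stage's tables under
#' `out_dir` plus a manifest of file content hashes. Re-running with the
#' same config yields a byte-identical output tree.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  # simulate
  sim <- generate_cohort(config$cohort)
  write_study(sim$study, file.path(out_dir, "cohort"))
  .write_tsv(sim$truth$triples, file.path(out_dir, "truth_triples.tsv"))
  .write_tsv(sim$truth$signflip, file.path(out_dir, "truth_signflip.tsv"))

  # preprocess
  study <- preprocess_study(sim$study, seed = seed + 1L)

  # predictors
  aging <- train_predictor(study, "aging", max_features = config$max_features,
                           folds = config$folds, k = config$k_knn,
                           seed = seed + 2L)
  disease <- train_predictor(study, "disease",
                             max_features = config$max_features,
                             folds = config$folds, k = config$k_knn,
                             seed = seed + 3L)
  pred_summary <- data.frame(
    task = c("aging", "disease"),
    selected_n = c(aging$ranked$selected_n, disease$ranked$selected_n),
    train_accuracy = c(aging$eval$train_accuracy,
                       disease$eval$train_accuracy),
    test_accuracy = c(aging$eval$test_accuracy, disease$eval$test_accuracy),
    auc = c(aging$eval$auc, disease$eval$auc))
  .write_tsv(pred_summary, file.path(out_dir, "predictors.tsv"))

  # oxidative candidates via the keyword route
  gmt <- synthetic_gmt(sim$truth, rownames(study$matrix),
                       seed = seed + 4L)
  gmt_path <- file.path(out_dir, "gene_sets.gmt")
  write_gmt(gmt, gmt_path)
  ox_candidates <- load_gene_sets_by_keyword(gmt_path,
                                             rownames(study$matrix))

  # triples
  trip <- assemble_triples(aging$markers, disease$markers, ox_candidates,
                           study, p_cut = config$p_cut,
                           fdr_cut = config$fdr_cut,
                           perm_p_cut = config$perm_p_cut,
                           n_perm = config$n_perm, seed = seed + 5L)
  .write_tsv(trip$triples, file.path(out_dir, "triples.tsv"))
  retained <- trip$triples[isTRUE_vec(trip$triples$retained), , drop = FALSE]

  # sensitivity
  sens <- NULL
  if (config$run_sensitivity && nrow(retained) > 0) {
    all_markers <- unique(c(retained$aging, retained$oxidative,
                            retained$disease))
    tr_cols <- study$samples$split == "train"
    dm <- intersect(disease$markers, rownames(study$matrix))
    t2 <- tr_cols & study$samples$phenotype == "T2DM"
    ct <- tr_cols & study$samples$phenotype == "control"
    mh <- mh_config(n_accept = config$n_accept, burn_in = config$burn_in,
                    proposal_scale = config$proposal_scale,
                    beta = config$beta, k = config$k_score)
    train_t <- study$matrix[dm, t2, drop = FALSE]
    train_c <- study$matrix[dm, ct, drop = FALSE]
    chain_markers <- unique(c(all_markers, dm))
    mh$seed <- seed + 6L
    prior_t <- fit_group_priors(study, chain_markers, "T2DM")
    chain_t <- run_mh_chain(prior_t, train_t, train_c, dm,
                            direction = 1, config = mh)
    mh$seed <- seed + 7L
    prior_c <- fit_group_priors(study, chain_markers, "control")
    chain_c <- run_mh_chain(prior_c, train_t, train_c, dm,
                            direction = -1, config = mh)
    sens <- triple_sensitivity(retained, chain_t, chain_c,
                               p_cut = config$p_cut,
                               fdr_cut = config$fdr_cut)
    .write_tsv(sens, file.path(out_dir, "sensitivity.tsv"))
  }

  # network, paths, betweenness
  net <- paths <- marker_table <- NULL
  if (config$run_network) {
    net <- build_diffcoexp_network(study, p_cut = config$p_cut,
                                   fdr_cut = config$fdr_cut,
                                   max_genes = config$network_max_genes)
    .write_tsv(net$edges, file.path(out_dir, "edges.tsv"))
    pair_df <- unique(retained[, c("oxidative", "disease")])
    names(pair_df) <- c("source", "target")
    paths <- shortest_paths_for_pairs(net, pair_df)
    path_df <- data.frame(
      pair = names(paths$paths),
      nodes = vapply(paths$paths, paste, character(1), collapse = ","))
    .write_tsv(path_df, file.path(out_dir, "paths.tsv"))
    if (length(paths$paths) > 0) {
      marker_table <- path_betweenness(paths)
      marker_table <- betweenness_null_p(net, marker_table,
                                         n_pairs = nrow(pair_df),
                                         n_perm = config$n_perm,
                                         seed = seed + 8L)
      .write_tsv(marker_table, file.path(out_dir, "network_markers.tsv"))
    }
  }

  # enrichment
  enr <- NULL
  if (config$run_enrichment && !is.null(paths) &&
      length(paths$paths) > 0) {
    enr <- enrich_gene_lists(paths$paths, gmt,
                             universe = rownames(study$matrix),
                             p_cut = config$p_cut,
                             fdr_cut = config$fdr_cut)
    .write_tsv(enr$records, file.path(out_dir, "enrichment.tsv"))
  }

  # pancancer
  pc <- NULL
  if (config$run_pancancer) {
    cfg <- config$cohort
    cohorts <- list(
      CANCER_A = generate_pancancer_cohort(
        cohort_config(n_genes = cfg$n_genes, seed = seed + 9L),
        hazard_beta = log(2)),
      CANCER_B = generate_pancancer_cohort(
        cohort_config(n_genes = cfg$n_genes, seed = seed + 10L),
        hazard_beta = 0))
    ox_markers <- unique(retained$oxidative)
    if (length(ox_markers) == 0) ox_markers <- disease$markers
    pc <- pancancer_run(cohorts,
                        markers = ox_markers,
                        gene_sets = gmt, p_cut = config$p_cut,
                        fdr_cut = config$fdr_cut)
    .write_tsv(pc$summary, file.path(out_dir, "pancancer_summary.tsv"))
  }

  # manifest: content hash of every produced file
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  .write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(study = study, truth = sim$truth, aging = aging,
                 disease = disease, triples = trip, sensitivity = sens,
                 network = net, paths = paths,
                 network_markers = marker_table, enrichment = enr,
                 pancancer = pc, manifest = manifest))
}

# treat NA as FALSE in logical subsetting
isTRUE_vec <- function(x) !is.na(x) & x
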