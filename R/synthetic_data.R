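#' Configuration for a synthetic oxidative-aging cohort
#'
#' The generator emulates the structure of a multi-cohort microarray study
#' of type 2 diabetes: four subgroups (aged/young crossed with
#' T2DM/control), a planted classification signal (mean shifts on marker
#' genes), planted aging -> oxidative -> disease mediation triples whose
#' coupling exists only in the T2DM condition, and gene pairs whose
#' correlation flips sign between conditions.
#'
#' Defaults give a desk-scale cohort with enough power for recovery tests:
#' 2,000 genes, subgroups of 60/40/40/20 samples, 20 mediation triples
#' with regression coefficients lambda = gamma = 0.9, a 1.0 z-unit
#' classifier shift, 30 sign-flip pairs at rho = 0.7, and residual noise
#' sd 0.5.
#'
#' @param n_genes Number of genes.
#' @param n_per_subgroup Integer vector of 4 subgroup sizes, in the order
#'   aged_control, young_control, aged_t2dm, young_t2dm.
#' @param n_true_triples Number of planted mediation triples.
#' @param lambda,gamma Mediation regression coefficients (T2DM only):
#'   oxidative = lambda * aging + noise; disease = gamma * oxidative + noise.
#' @param delta Classifier shift in expression z-units: disease markers are
#'   shifted +delta in T2DM samples, aging markers +delta in aged samples.
#' @param n_signflip_pairs Number of planted sign-flipping gene pairs.
#' @param signflip_rho Magnitude of the planted pair correlation
#'   (+rho in controls, -rho in T2DM), in (0, 1).
#' @param noise_sd Residual noise sd in z-units.
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_genes = 2000,
                          n_per_subgroup = c(aged_control = 60,
                                             young_control = 40,
                                             aged_t2dm = 40,
                                             young_t2dm = 20),
                          n_true_triples = 20,
                          lambda = 0.9,
                          gamma = 0.9,
                          delta = 1.0,
                          n_signflip_pairs = 30,
                          signflip_rho = 0.7,
                          noise_sd = 0.5,
                          seed = 1L) {
  stopifnot(n_genes >= 1, length(n_per_subgroup) == 4,
            all(n_per_subgroup >= 0), n_true_triples >= 0,
            n_signflip_pairs >= 0, noise_sd > 0,
            signflip_rho > 0, signflip_rho < 1)
  if (sum(n_per_subgroup) < 10) {
    stop("config error: subgroup sizes must sum to at least 10")
  }
  if (3 * n_true_triples + 2 * n_signflip_pairs > n_genes) {
    stop("config error: not enough genes for the requested planted structure")
  }
  n_per_subgroup <- stats::setNames(as.integer(n_per_subgroup),
                                    c("aged_control", "young_control",
                                      "aged_t2dm", "young_t2dm"))
  structure(list(n_genes = as.integer(n_genes),
                 n_per_subgroup = n_per_subgroup,
                 n_true_triples = as.integer(n_true_triples),
                 lambda = lambda, gamma = gamma, delta = delta,
                 n_signflip_pairs = as.integer(n_signflip_pairs),
                 signflip_rho = signflip_rho, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

.gene_ids <- function(n) sprintf("G%05d", seq_len(n))

# Draws planted gene ids; consumes a fixed amount of the RNG stream so
# generate_cohort() and planted_truth() stay in lockstep.
.plant_ids <- function(config) {
  ids <- .gene_ids(config$n_genes)
  n_planted <- 3 * config$n_true_triples + 2 * config$n_signflip_pairs
  planted <- if (n_planted > 0) sample(config$n_genes, n_planted) else integer(0)
  nt <- config$n_true_triples
  triples <- if (nt > 0) {
    data.frame(aging = ids[planted[seq_len(nt)]],
               oxidative = ids[planted[nt + seq_len(nt)]],
               disease = ids[planted[2 * nt + seq_len(nt)]],
               stringsAsFactors = FALSE)
  } else {
    data.frame(aging = character(0), oxidative = character(0),
               disease = character(0))
  }
  ns <- config$n_signflip_pairs
  off <- 3 * nt
  signflip <- if (ns > 0) {
    data.frame(gene_a = ids[planted[off + seq_len(ns)]],
               gene_b = ids[planted[off + ns + seq_len(ns)]],
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_a = character(0), gene_b = character(0))
  }
  list(triples = triples, signflip = signflip)
}

#' Generate a synthetic four-subgroup expression cohort
#'
#' Baseline expression is standard normal. For each planted triple
#' (a, o, d): in T2DM samples o = lambda * a + eps and d = gamma * o + eps
#' with eps ~ Normal(0, noise_sd), while in controls a, o, d are mutually
#' independent. Disease markers are additionally shifted +delta in T2DM
#' samples and aging markers +delta in aged samples. Sign-flip pairs have
#' correlation +rho in controls and -rho in T2DM. Output is deterministic
#' given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list with `study` (an `expression_study`: `matrix`
#'   genes x samples plus a `samples` metadata data.frame) and `truth`
#'   (the planted `triples` and `signflip` tables).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  plant <- .plant_ids(config)

  nsub <- config$n_per_subgroup
  n <- sum(nsub)
  subgroup <- rep(names(nsub), nsub)
  aged <- grepl("^aged", subgroup)
  t2dm <- grepl("t2dm$", subgroup)
  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    age = ifelse(aged, sample(51:85, n, replace = TRUE),
                 sample(20:50, n, replace = TRUE)),
    phenotype = ifelse(t2dm, "T2DM", "control"),
    cohort = "synthetic",
    split = "unassigned",
    stringsAsFactors = FALSE
  )

  ids <- .gene_ids(config$n_genes)
  mat <- matrix(stats::rnorm(config$n_genes * n), nrow = config$n_genes,
                dimnames = list(ids, samples$sample_id))

  sd_e <- config$noise_sd
  # mediation triples: the coupling is planted on the baseline z-scale,
  # and the classifier mean shifts are overlaid afterwards, so each
  # planted feature perturbs only the statistic it is meant to exercise
  for (i in seq_len(nrow(plant$triples))) {
    tr <- plant$triples[i, ]
    a <- stats::rnorm(n)
    o <- d <- numeric(n)
    o[!t2dm] <- stats::rnorm(sum(!t2dm))
    d[!t2dm] <- stats::rnorm(sum(!t2dm))
    o[t2dm] <- config$lambda * a[t2dm] + stats::rnorm(sum(t2dm), sd = sd_e)
    d[t2dm] <- config$gamma * o[t2dm] + stats::rnorm(sum(t2dm), sd = sd_e)
    mat[tr$aging, ] <- a + config$delta * aged
    mat[tr$oxidative, ] <- o
    mat[tr$disease, ] <- d + config$delta * t2dm
  }
  # sign-flip pairs: +rho in controls, -rho in T2DM
  rho <- config$signflip_rho
  for (i in seq_len(nrow(plant$signflip))) {
    pr <- plant$signflip[i, ]
    g1 <- stats::rnorm(n)
    sgn <- ifelse(t2dm, -1, 1)
    g2 <- sgn * rho * g1 + sqrt(1 - rho^2) * stats::rnorm(n)
    mat[pr$gene_a, ] <- g1
    mat[pr$gene_b, ] <- g2
  }

  study <- expression_study(mat, samples)
  truth <- structure(list(triples = plant$triples,
                          signflip = plant$signflip),
                     class = "truth_table")
  list(study = study, truth = truth)
}

#' Ground truth planted by a cohort configuration
#'
#' Recomputes, deterministically from the seed, exactly the gene ids that
#' [generate_cohort()] plants for the same `config`.
#'
#' @param config A [cohort_config()].
#' @return A `truth_table` with `triples` and `signflip` tables.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  plant <- .plant_ids(config)
  structure(list(triples = plant$triples, signflip = plant$signflip),
            class = "truth_table")
}

#' Generate a synthetic tumor/normal cohort with survival metadata
#'
#' Expression is on the log2(x + 1) scale. Planted differentially
#' expressed genes have a tumor/normal mean ratio of `de_fold` on the
#' linear scale. Survival times for tumor samples are exponential with
#' log-hazard `hazard_beta` per unit of the standardized mean expression
#' over the planted DE genes (the designated marker score); censoring is
#' uniform on (0, 2 x median event time).
#'
#' @param config A [cohort_config()]; supplies `n_genes`, `noise_sd`,
#'   `seed`.
#' @param n_tumor,n_normal Sample counts (n_normal >= 1).
#' @param n_de Number of planted DE genes (default 50).
#' @param de_fold Linear-scale fold change of planted genes (default 4).
#' @param hazard_beta Log-hazard per score unit (default log(2)).
#' @param baseline_hazard Event rate per day at score 0 (default
#'   log(2)/730, i.e. two-year median survival).
#' @return A list with `study` (tumor + normal columns; metadata carries
#'   `condition`, `time`, `event`) and `truth` (`de_genes`,
#'   `survival_markers`, `survival_beta`).
#' @export
generate_pancancer_cohort <- function(config, n_tumor = 50, n_normal = 50,
                                      n_de = 50, de_fold = 4,
                                      hazard_beta = log(2),
                                      baseline_hazard = log(2) / 730) {
  stopifnot(inherits(config, "cohort_config"))
  if (n_normal < 1) stop("config error: n_normal must be >= 1")
  if (de_fold <= 0) stop("config error: de_fold must be positive")
  if (baseline_hazard <= 0) stop("config error: baseline hazard must be positive")
  if (n_de > config$n_genes) stop("config error: n_de exceeds n_genes")
  set.seed(config$seed)
  ids <- .gene_ids(config$n_genes)
  de_idx <- if (n_de > 0) sample(config$n_genes, n_de) else integer(0)

  n <- n_tumor + n_normal
  base_mu <- stats::runif(config$n_genes, 4, 8)
  mat <- matrix(stats::rnorm(config$n_genes * n, sd = config$noise_sd),
                nrow = config$n_genes) + base_mu
  is_tumor <- c(rep(TRUE, n_tumor), rep(FALSE, n_normal))
  mat[de_idx, is_tumor] <- mat[de_idx, is_tumor] + log2(de_fold)
  dimnames(mat) <- list(ids, sprintf("%s%03d",
                                     ifelse(is_tumor, "TUM", "NRM"),
                                     seq_len(n)))

  score <- colMeans(mat[de_idx, is_tumor, drop = FALSE])
  z <- if (length(de_idx) > 0 && stats::sd(score) > 0) {
    as.numeric(scale(score))
  } else {
    rep(0, n_tumor)
  }
  rate <- baseline_hazard * exp(hazard_beta * z)
  event_time <- stats::rexp(n_tumor, rate = rate)
  cens_time <- stats::runif(n_tumor, 0, 2 * stats::median(event_time))
  time <- pmin(event_time, cens_time)
  event <- as.integer(event_time <= cens_time)

  samples <- data.frame(
    sample_id = colnames(mat),
    age = NA_real_,
    phenotype = ifelse(is_tumor, "tumor", "normal"),
    cohort = "synthetic_cancer",
    split = "unassigned",
    time = c(time, rep(NA_real_, n_normal)),
    event = c(event, rep(NA_integer_, n_normal)),
    stringsAsFactors = FALSE
  )
  study <- expression_study(mat, samples)
  truth <- structure(list(de_genes = ids[de_idx],
                          survival_markers = ids[de_idx],
                          survival_beta = hazard_beta),
                     class = "truth_table")
  list(study = study, truth = truth)
}
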