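#' Metropolis-Hastings configuration
#'
#' @param n_accept Accepted samples retained per chain (default 1000).
#' @param burn_in Accepted samples discarded before retention
#'   (default 500).
#' @param proposal_scale Random-walk proposal sd as a multiple of each
#'   marker's prior sd (default 0.25).
#' @param beta Weight of the disease score in the target density
#'   (default 1.0; 0 makes the target the prior itself).
#' @param k Neighbor count of the disease score (default 7).
#' @param thin Keep every `thin`-th post-burn-in state (default 1).
#'   Downstream rank tests assume roughly independent draws, so
#'   calibration studies should thin enough to break the random-walk
#'   autocorrelation.
#' @param seed Integer seed.
#' @return An `mh_config` list.
#' @export
mh_config <- function(n_accept = 1000, burn_in = 500, proposal_scale = 0.25,
                      beta = 1.0, k = 7, thin = 1, seed = 1L) {
  stopifnot(n_accept > 0, burn_in >= 0, proposal_scale > 0, k >= 1,
            thin >= 1)
  structure(list(n_accept = as.integer(n_accept),
                 burn_in = as.integer(burn_in),
                 proposal_scale = proposal_scale, beta = beta,
                 k = as.integer(k), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mh_config")
}

#' Per-group normal priors over the identified markers
#'
#' Sample mean and sd of each marker over the group's samples
#' (training split if assigned). Zero-variance markers are dropped with a
#' warning.
#'
#' @param study An [expression_study()].
#' @param markers Character vector of marker symbols.
#' @param group Phenotype label selecting the samples.
#' @param use_split Restrict to `split == "train"` when available
#'   (default TRUE).
#' @return A `group_prior` list: `mean`, `sd` (named numeric vectors).
#' @export
fit_group_priors <- function(study, markers, group, use_split = TRUE) {
  sel <- study$samples$phenotype == group
  if (use_split && "split" %in% names(study$samples) &&
      any(study$samples$split == "train")) {
    sel <- sel & study$samples$split == "train"
  }
  if (sum(sel) < 2) stop("need >= 2 samples in group '", group, "'")
  sub <- study$matrix[markers, sel, drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance marker(s) dropped from the prior")
  }
  structure(list(mean = mu[keep], sd = sdv[keep]), class = "group_prior")
}

#' Nearest-neighbour disease score of a candidate marker vector
#'
#' Sum of Euclidean distances to the `k` nearest control training samples
#' minus the same sum over the `k` nearest T2DM training samples, both
#' computed over the disease markers. Positive scores mean the candidate
#' sits closer to the T2DM cloud.
#'
#' @param candidate Numeric marker vector.
#' @param train_t2dm,train_control Marker x sample matrices of training
#'   data (same marker order as `candidate`).
#' @param k Neighbors per group (default 7; must not exceed either group).
#' @return Numeric score (unitless).
#' @export
disease_score <- function(candidate, train_t2dm, train_control, k = 7) {
  if (k > ncol(train_t2dm) || k > ncol(train_control)) {
    stop("k = ", k, " exceeds a training group size (",
         ncol(train_t2dm), " T2DM / ", ncol(train_control), " control)")
  }
  d_t <- sqrt(colSums((train_t2dm - candidate)^2))
  d_c <- sqrt(colSums((train_control - candidate)^2))
  sum(sort(d_c)[seq_len(k)]) - sum(sort(d_t)[seq_len(k)])
}

#' Run one Metropolis-Hastings chain over marker space
#'
#' Target density proportional to
#' prior(theta) * exp(direction * beta * disease_score(theta)); the
#' Gaussian random-walk proposal is symmetric so the transition-kernel
#' ratio cancels from the acceptance probability
#' alpha = min(1, target(theta*) / target(theta)). The chain starts at
#' the prior mean; the first `burn_in` states are discarded and exactly
#' `n_accept` post-burn-in chain states are returned. Rejected proposals
#' repeat the current state, as detailed balance requires; recording only
#' acceptance events would oversample the target's tails. Deterministic
#' given the config seed.
#'
#' @param prior A `group_prior` from [fit_group_priors()].
#' @param train_t2dm,train_control Disease-marker training matrices for
#'   the score (rows = `score_genes`).
#' @param score_genes Marker symbols over which the disease score is
#'   computed (subset of the prior's markers).
#' @param direction +1 for the T2DM-enriched chain, -1 for the
#'   control-enriched chain.
#' @param config An [mh_config()].
#' @return A `chain_samples` list: `samples` (n_accept x markers matrix),
#'   `scores`, `acceptance_rate`.
#' @export
run_mh_chain <- function(prior, train_t2dm, train_control, score_genes,
                         direction = 1, config = mh_config()) {
  markers <- names(prior$mean)
  score_idx <- match(score_genes, markers)
  if (anyNA(score_idx)) stop("score_genes must be a subset of the prior markers")
  beta <- config$beta
  k <- config$k
  log_target <- function(theta) {
    lp <- sum(stats::dnorm(theta, prior$mean, prior$sd, log = TRUE))
    if (beta == 0) return(list(lt = lp, score = NA_real_))
    sc <- disease_score(theta[score_idx], train_t2dm, train_control, k)
    list(lt = lp + direction * beta * sc, score = sc)
  }

  set.seed(config$seed)
  prop_sd <- config$proposal_scale * prior$sd
  theta <- prior$mean
  cur <- log_target(theta)
  if (!is.finite(cur$lt)) stop("non-finite target at initialization")

  thin <- config$thin
  total <- config$burn_in + config$n_accept * thin
  out <- matrix(NA_real_, nrow = config$n_accept, ncol = length(markers),
                dimnames = list(NULL, markers))
  scores <- numeric(config$n_accept)
  n_acc <- 0L
  kept <- 0L
  for (it in seq_len(total)) {
    proposal <- theta + stats::rnorm(length(theta), 0, prop_sd)
    cand <- log_target(proposal)
    if (log(stats::runif(1)) < cand$lt - cur$lt) {
      theta <- proposal
      cur <- cand
      n_acc <- n_acc + 1L
    }
    if (it > config$burn_in && (it - config$burn_in) %% thin == 0) {
      kept <- kept + 1L
      out[kept, ] <- theta
      scores[kept] <- cur$score
    }
  }
  structure(list(samples = out, scores = scores,
                 acceptance_rate = n_acc / total),
            class = "chain_samples")
}

#' Correlation index of a triple over sampled marker vectors
#'
#' For each accepted sample, (disease - aging) / (oxidative - aging); the
#' denominator is clipped to sign(denominator) * max(|denominator|, eps)
#' so degenerate samples yield large finite ratios rather than Inf.
#'
#' @param a,o,d Numeric vectors of the aging, oxidative and disease
#'   marker values across accepted samples.
#' @param eps Denominator clip (default 1e-8).
#' @return Numeric vector of ratios.
#' @export
correlation_index <- function(a, o, d, eps = 1e-8) {
  den <- o - a
  s <- ifelse(den >= 0, 1, -1)
  den <- s * pmax(abs(den), eps)
  (d - a) / den
}

.winsorize <- function(x, lower = 0.01, upper = 0.99) {
  q <- stats::quantile(x, c(lower, upper), names = FALSE, type = 7)
  pmin(pmax(x, q[1]), q[2])
}

#' Sensitivity test of each triple between the two chains
#'
#' Per triple, computes the correlation index over both chains' accepted
#' samples (winsorized at each chain's 1st/99th percentiles), compares
#' the two sample sets with the Kruskal-Wallis test, BH-adjusts across
#' all triples, and reports the winsorized mean difference
#' (T2DM chain - control chain).
#'
#' @param triples Data frame with `aging`, `oxidative`, `disease`
#'   columns.
#' @param chain_t2dm,chain_control `chain_samples` from
#'   [run_mh_chain()].
#' @param p_cut,fdr_cut Thresholds (defaults 0.05, 0.1).
#' @return Data frame: triple genes, `kw_p`, `fdr`, `difference`,
#'   `sensitive`.
#' @export
triple_sensitivity <- function(triples, chain_t2dm, chain_control,
                               p_cut = 0.05, fdr_cut = 0.1) {
  if (nrow(triples) == 0) stop("no triples to evaluate")
  st <- chain_t2dm$samples
  sc <- chain_control$samples
  if (nrow(st) == 0 || nrow(sc) == 0) stop("empty chains")
  res <- lapply(seq_len(nrow(triples)), function(i) {
    g <- triples[i, c("aging", "oxidative", "disease")]
    ci_t <- .winsorize(correlation_index(st[, g$aging], st[, g$oxidative],
                                         st[, g$disease]))
    ci_c <- .winsorize(correlation_index(sc[, g$aging], sc[, g$oxidative],
                                         sc[, g$disease]))
    kt <- kw_test(c(ci_t, ci_c),
                  rep(c("T2DM", "control"), c(length(ci_t), length(ci_c))))
    c(p = kt$p_value, difference = mean(ci_t) - mean(ci_c))
  })
  res <- do.call(rbind, res)
  out <- data.frame(triples[, c("aging", "oxidative", "disease")],
                    kw_p = res[, "p"],
                    fdr = bh_adjust(res[, "p"])$adjusted,
                    difference = res[, "difference"])
  out$sensitive <- out$kw_p < p_cut & out$fdr < fdr_cut
  rownames(out) <- NULL
  out
}
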