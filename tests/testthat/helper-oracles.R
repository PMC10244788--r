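# Brute-force oracles, independent of the package's implementations.

# Kruskal-Wallis H with tie correction, from the rank definition.
oracle_kw <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  h <- 0
  for (g in unique(groups)) {
    idx <- groups == g
    h <- h + sum(idx) * (mean(r[idx]) - (n + 1) / 2)^2
  }
  h <- 12 / (n * (n + 1)) * h
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) return(c(statistic = 0, p = 1))
  h <- h / corr
  c(statistic = h, p = pchisq(h, df = 1, lower.tail = FALSE))
}

# Pearson r and two-sided t-test p from first principles.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * pt(-abs(tt), df = n - 2))
}

# BH by the sort / scale / cumulative-min / unsort definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Upper-tail hypergeometric by direct enumeration (N small).
oracle_hyper <- function(N, M, n, k) {
  ks <- k:min(M, n)
  sum(choose(M, ks) * choose(N - M, n - ks)) / choose(N, n)
}

# AUC by pairwise counting with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive correlation-distance kNN prediction for one query column.
oracle_knn <- function(train, labels, query, k) {
  d <- apply(train, 2, function(tr) {
    r <- suppressWarnings(cor(tr, query))
    if (is.na(r)) 2 else 1 - r
  })
  nn <- order(d)[seq_len(k)]
  score <- mean(labels[nn])
  label <- if (score > 0.5) 1L else if (score < 0.5) 0L else labels[nn[1]]
  list(label = label, score = score)
}

# Log-rank observed-minus-expected tabulation for two groups.
oracle_logrank <- function(time, event, group) {
  lv <- sort(unique(group))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == lv[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == lv[1])
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  c(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# small expression_study fixture from a plain matrix
make_study <- function(mat, phenotype, age = NULL, split = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%03d", seq_len(ncol(mat)))
  meta <- data.frame(sample_id = colnames(mat),
                     age = if (is.null(age)) rep(40, ncol(mat)) else age,
                     phenotype = phenotype,
                     cohort = "fix",
                     split = if (is.null(split)) "unassigned" else split,
                     stringsAsFactors = FALSE)
  expression_study(mat, meta)
}
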