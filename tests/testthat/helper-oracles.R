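# Independent brute-force oracles used to validate the implementation.
# These are deliberately written as plain elementwise loops, separate from
# the vectorized implementation paths.

# Weighted-KS enrichment score: explicit walk down the ranked list,
# recording the running sum after every position. Shares the package's
# stated tie-break convention: when the positive and negative extrema tie
# in magnitude (1e-9 relative), the positive one is reported.
oracle_es <- function(stats, sig_genes, weight = 1) {
  genes <- names(stats)
  in_sig <- genes %in% sig_genes
  nh <- sum(in_sig)
  N <- length(stats)
  denom <- sum(abs(stats[in_sig])^weight)
  phit <- 0
  pmiss <- 0
  mx <- -Inf
  mn <- Inf
  for (i in seq_len(N)) {
    if (in_sig[i]) {
      phit <- phit + if (denom > 0) abs(stats[i])^weight / denom else 1 / nh
    } else {
      pmiss <- pmiss + 1 / (N - nh)
    }
    d <- unname(phit - pmiss)
    if (d > mx) mx <- d
    if (d < mn) mn <- d
  }
  tol <- 1e-9 * max(mx, -mn, 1)
  if (mx - (-mn) >= -tol) mx else mn
}

# Signal-to-noise ranking metric, one gene at a time.
oracle_s2n <- function(mat, ids_a, ids_b) {
  out <- numeric(nrow(mat))
  for (g in seq_len(nrow(mat))) {
    xa <- mat[g, ids_a]
    xb <- mat[g, ids_b]
    sa <- max(stats::sd(xa), 0.2 * abs(mean(xa)), 1e-8)
    sb <- max(stats::sd(xb), 0.2 * abs(mean(xb)), 1e-8)
    out[g] <- (mean(xa) - mean(xb)) / (sa + sb)
  }
  names(out) <- rownames(mat)
  out
}

# Exhaustive phenotype-permutation NES and p for one signature: enumerate
# every assignment of n_a of the pooled samples to group a.
oracle_exhaustive_gsea <- function(mat, ids_a, ids_b, sig_genes, weight = 1) {
  pooled <- c(ids_a, ids_b)
  n_a <- length(ids_a)
  rank_and_score <- function(a_ids, b_ids) {
    s <- oracle_s2n(mat, a_ids, b_ids)
    ord <- order(-s, names(s), method = "radix")
    oracle_es(s[ord], sig_genes, weight)
  }
  es_obs <- rank_and_score(ids_a, ids_b)
  idx <- utils::combn(length(pooled), n_a)
  es_null <- apply(idx, 2, function(ia) {
    rank_and_score(pooled[ia], pooled[-ia])
  })
  same <- if (es_obs >= 0) es_null >= 0 else es_null < 0
  list(es = unname(es_obs),
       nes = unname(es_obs / mean(abs(es_null[same]))),
       p = unname((1 + sum(abs(es_null[same]) >= abs(es_obs))) /
                    (1 + sum(same))))
}

# Exact two-sided Mann-Whitney p by enumerating every group assignment of
# the pooled values (no-ties inputs).
oracle_mw_p <- function(xa, xb) {
  pooled <- c(xa, xb)
  m <- length(xa)
  u_stat <- function(a, b) {
    u <- 0
    for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
    u
  }
  u_obs <- u_stat(xa, xb)
  idx <- utils::combn(length(pooled), m)
  u_null <- apply(idx, 2, function(ia) u_stat(pooled[ia], pooled[-ia]))
  p_lo <- mean(u_null <= u_obs)
  p_hi <- mean(u_null >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# AUC by concordant-pair counting.
oracle_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Spearman rho as Pearson correlation of average ranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"), method = "pearson")
}

# Small dense expression fixture: deterministic values, distinct genes.
toy_matrix <- function(n_genes = 20, n_samples = 8, seed = 42) {
  set.seed(seed)
  mat <- matrix(stats::rnorm(n_genes * n_samples, mean = 6),
                nrow = n_genes,
                dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                sprintf("S%02d", seq_len(n_samples))))
  mat
}

toy_metadata <- function(mat, groups) {
  data.frame(sample_id = colnames(mat),
             group = rep(groups, length.out = ncol(mat)),
             stringsAsFactors = FALSE)
}

# Reduced-size null-cohort config used in calibration checks.
null_calibration_config <- function(seed) {
  simulation_config(n_genes = 500,
                    cell_types = c("Monocytes", "aDC", "pDC", "B.cells"),
                    group_sizes = c(A = 10, B = 10),
                    shift = list(), delta = 0, seed = seed)
}
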