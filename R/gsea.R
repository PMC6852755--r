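# Two-sample gene set enrichment analysis: ranking metric, weighted
# Kolmogorov-Smirnov running sum, phenotype-permutation NES/p, and
# per-cell-type aggregation.

# Internal ranking statistics. X is genes x samples; ia/ib are column indices
# of the two groups. All return one value per gene (a vs b orientation).
.stat_s2n <- function(X, ia, ib) {
  ma <- rowMeans(X[, ia, drop = FALSE])
  mb <- rowMeans(X[, ib, drop = FALSE])
  sa <- pmax(row_sds(X[, ia, drop = FALSE]), 0.2 * abs(ma), 1e-8)
  sb <- pmax(row_sds(X[, ib, drop = FALSE]), 0.2 * abs(mb), 1e-8)
  (ma - mb) / (sa + sb)
}

.stat_log2fc <- function(X, ia, ib) {
  rowMeans(X[, ia, drop = FALSE]) - rowMeans(X[, ib, drop = FALSE])
}

.stat_tstat <- function(X, ia, ib) {
  ma <- rowMeans(X[, ia, drop = FALSE])
  mb <- rowMeans(X[, ib, drop = FALSE])
  va <- row_sds(X[, ia, drop = FALSE])^2
  vb <- row_sds(X[, ib, drop = FALSE])^2
  se <- sqrt(va / length(ia) + vb / length(ib))
  (ma - mb) / pmax(se, 1e-8)
}

.metric_fun <- function(metric) {
  switch(metric,
         s2n = .stat_s2n,
         log2fc = .stat_log2fc,
         tstat = .stat_tstat,
         stop("unknown ranking metric: ", metric, call. = FALSE))
}

#' Rank genes by a two-group differential metric
#'
#' Default metric is signal-to-noise, `(mean_a - mean_b) / (sd_a + sd_b)`,
#' with each group's standard deviation floored at
#' `max(0.2 * |group mean|, 1e-8)` so flat genes cannot dominate the
#' ranking. Genes are returned in descending metric order; ties are broken
#' by gene identifier (lexicographic, C locale) for determinism.
#'
#' @param mat numeric expression matrix, genes x samples.
#' @param metadata data.frame with `sample_id` and the grouping column.
#' @param group_a,group_b labels of the two groups; the metric is oriented
#'   a-minus-b, so positive values mean higher in `group_a`.
#' @param group_col metadata column holding the group label (default
#'   `"group"`).
#' @param metric `"s2n"` (default), `"log2fc"`, or `"tstat"`.
#' @return named numeric vector of metric values, sorted descending; names
#'   are gene identifiers.
#' @export
rank_genes <- function(mat, metadata, group_a, group_b, group_col = "group",
                       metric = c("s2n", "log2fc", "tstat")) {
  metric <- match.arg(metric)
  metadata <- align_metadata(mat, metadata)
  if (!group_col %in% colnames(metadata)) {
    stop("metadata lacks grouping column '", group_col, "'", call. = FALSE)
  }
  ids_a <- metadata$sample_id[metadata[[group_col]] == group_a]
  ids_b <- metadata$sample_id[metadata[[group_col]] == group_b]
  if (length(ids_a) < 2L || length(ids_b) < 2L) {
    stop("each group needs >= 2 samples (", group_a, ": ", length(ids_a),
         ", ", group_b, ": ", length(ids_b), ")", call. = FALSE)
  }
  ia <- match(ids_a, colnames(mat))
  ib <- match(ids_b, colnames(mat))
  s <- .metric_fun(metric)(mat, ia, ib)
  genes <- norm_gene_ids(rownames(mat))
  ord <- order_desc_ties_by_name(s, genes)
  stats::setNames(s[ord], genes[ord])
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list top to bottom; at a signature gene ("hit") the
#' running sum gains `|r_i|^weight / sum_hits |r_j|^weight`, at a miss it
#' loses `1 / (N - N_hits)`. The enrichment score is the running sum's
#' signed maximum deviation from zero. With `weight = 0` this is the
#' classical unweighted KS statistic and depends only on rank positions.
#'
#' @param stats named numeric vector of ranking-metric values sorted
#'   descending (as returned by [rank_genes()]).
#' @param genes character vector of signature genes (canonicalized
#'   internally).
#' When the positive and negative extrema of the running sum tie in
#' magnitude (to within 1e-9 relative), the positive extremum is reported;
#' a fixed tie-break keeps the score deterministic under floating-point
#' reordering.
#'
#' @param weight exponent on `|r_i|` for hit increments (default 1).
#' @return list with `es` (the enrichment score, in `[-1, 1]`), `profile`
#'   (running-sum vector, one value per ranked gene) and `hits` (logical
#'   hit indicator along the list).
#' @export
enrichment_score <- function(stats, genes, weight = 1) {
  universe <- norm_gene_ids(names(stats))
  hit <- universe %in% norm_gene_ids(genes)
  nh <- sum(hit)
  N <- length(stats)
  if (nh == 0L) stop("signature has no overlap with the ranked universe", call. = FALSE)
  if (nh == N) stop("empty complement: signature covers the whole universe", call. = FALSE)
  w <- abs(stats)^weight
  hit_inc <- ifelse(hit, w, 0)
  denom <- sum(hit_inc)
  if (denom > 0) {
    hit_inc <- hit_inc / denom
  } else {
    hit_inc[hit] <- 1 / nh # all hit weights zero: fall back to uniform mass
  }
  profile <- cumsum(hit_inc - ifelse(hit, 0, 1 / (N - nh)))
  list(es = .signed_extremum(profile), profile = unname(profile), hits = hit)
}

# Signed maximum deviation of a running sum; magnitude ties (to 1e-9
# relative) resolve to the positive extremum.
.signed_extremum <- function(profile) {
  mx <- max(profile)
  mn <- min(profile)
  tol <- 1e-9 * max(mx, -mn, 1)
  if (mx - (-mn) >= -tol) unname(mx) else unname(mn)
}

# Restrict a collection to signatures with adequate overlap with the
# universe; warns (once per signature) about the skipped ones.
.overlap_filter <- function(collection, universe, min_overlap) {
  ov <- vapply(collection$sets, function(g) sum(universe %in% g), integer(1L))
  skip <- ov < min_overlap | ov == length(universe)
  if (any(skip)) {
    warning("skipping ", sum(skip), " signature(s) with overlap < ",
            min_overlap, " genes (or full-universe overlap): ",
            paste(names(collection$sets)[skip], collapse = ", "),
            call. = FALSE)
  }
  list(keep = names(collection$sets)[!skip], overlap = ov)
}

# Label assignments for the permutation null: a matrix with one column per
# permutation, rows = indices (into the pooled sample vector) assigned to
# group a. Exhaustive when the number of distinct assignments fits in
# n_perm, otherwise Monte Carlo.
.perm_assignments <- function(n, n_a, n_perm, exhaustive) {
  n_all <- choose(n, n_a)
  use_exhaustive <- switch(exhaustive,
                           always = TRUE,
                           never = FALSE,
                           auto = n_all <= n_perm)
  if (use_exhaustive) {
    list(idx = utils::combn(n, n_a), exhaustive = TRUE)
  } else {
    list(idx = replicate(n_perm, sample.int(n, n_a)), exhaustive = FALSE)
  }
}

#' Two-sample GSEA over a signature collection
#'
#' For every signature with sufficient overlap, computes the weighted-KS
#' enrichment score on the observed group ranking, then permutes the
#' phenotype labels, re-ranks and re-scores to form the null. The
#' normalized enrichment score divides the observed ES by the mean |ES| of
#' same-sign permutations; the nominal p is one-sided on the observed sign
#' with +1 smoothing:
#' `p = (1 + #{same-sign |ES_perm| >= |ES|}) / (1 + #same-sign)`.
#'
#' When the number of distinct label assignments is at most `n_perm` (e.g.
#' 3 vs 3 gives 20), the null is enumerated exhaustively instead of
#' sampled, so the p-value is exact.
#'
#' @inheritParams rank_genes
#' @param collection a [signature_collection()].
#' @param n_perm number of phenotype permutations (>= 100; default 1000).
#' @param seed mandatory integer seed for the permutation generator.
#' @param weight hit-weight exponent (default 1).
#' @param min_overlap signatures with fewer genes present in the matrix are
#'   skipped with a warning (default 5).
#' @param exhaustive `"auto"` (default: enumerate all label assignments
#'   when they fit in `n_perm`), `"always"`, or `"never"`.
#' @return data.frame with one row per scored signature: `signature`,
#'   `cell_type`, `es`, `nes`, `p`, `padj` (Benjamini-Hochberg across the
#'   scored signatures), `n_genes_used`, `n_perm`.
#' @export
gsea <- function(mat, metadata, collection, group_a, group_b,
                 group_col = "group", metric = c("s2n", "log2fc", "tstat"),
                 n_perm = 1000, seed, weight = 1, min_overlap = 5,
                 exhaustive = c("auto", "always", "never")) {
  metric <- match.arg(metric)
  exhaustive <- match.arg(exhaustive)
  if (missing(seed)) stop("a seed is required for the permutation null", call. = FALSE)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  set.seed(as.integer(seed))

  metadata <- align_metadata(mat, metadata)
  ids_a <- metadata$sample_id[metadata[[group_col]] == group_a]
  ids_b <- metadata$sample_id[metadata[[group_col]] == group_b]
  if (length(ids_a) < 2L || length(ids_b) < 2L) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  if (min(length(ids_a), length(ids_b)) < 7L) {
    warning("group with < 7 samples: the phenotype-permutation null is coarse",
            call. = FALSE)
  }
  pooled <- c(ids_a, ids_b)
  X <- mat[, pooled, drop = FALSE]
  n_a <- length(ids_a)
  n <- length(pooled)
  stat_fun <- .metric_fun(metric)
  genes <- norm_gene_ids(rownames(X))

  flt <- .overlap_filter(collection, genes, min_overlap)
  keep <- flt$keep
  if (!length(keep)) stop("no signature passes the overlap filter", call. = FALSE)
  members <- lapply(collection$sets[keep], function(g) genes %in% g)

  score_assignment <- function(ia) {
    s <- stat_fun(X, ia, setdiff(seq_len(n), ia))
    ord <- order_desc_ties_by_name(s, genes)
    s_ord <- s[ord]
    vapply(members, function(m) {
      hit <- m[ord]
      nh <- sum(hit)
      w <- abs(s_ord)^weight
      hi <- ifelse(hit, w, 0)
      denom <- sum(hi)
      if (denom > 0) hi <- hi / denom else hi[hit] <- 1 / nh
      .signed_extremum(cumsum(hi - ifelse(hit, 0, 1 / (length(s_ord) - nh))))
    }, numeric(1L))
  }

  obs <- score_assignment(seq_len(n_a))
  perms <- .perm_assignments(n, n_a, n_perm, exhaustive)
  null_es <- apply(perms$idx, 2L, score_assignment)
  if (length(keep) == 1L) null_es <- matrix(null_es, nrow = 1L)
  n_perm_used <- ncol(perms$idx)

  nes <- p <- rep(NA_real_, length(keep))
  for (k in seq_along(keep)) {
    es_k <- obs[k]
    same <- if (es_k >= 0) null_es[k, ] >= 0 else null_es[k, ] < 0
    n_same <- sum(same)
    if (n_same == 0L || es_k == 0) {
      warning("no same-sign permutation for signature '", keep[k],
              "': NES undefined", call. = FALSE)
      p[k] <- 1
      next
    }
    nes[k] <- es_k / mean(abs(null_es[k, same]))
    p[k] <- (1 + sum(abs(null_es[k, same]) >= abs(es_k))) / (1 + n_same)
  }

  data.frame(signature = keep,
             cell_type = unname(collection$cell_type[keep]),
             es = unname(obs),
             nes = nes,
             p = p,
             padj = stats::p.adjust(p, method = "BH"),
             n_genes_used = unname(flt$overlap[keep]),
             n_perm = n_perm_used,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Average enrichment results within cell types
#'
#' Cell-type summaries take the arithmetic mean of NES and of the nominal p
#' over that cell type's scored signatures (skipped signatures never enter
#' the denominator).
#'
#' @param results data.frame as returned by [gsea()].
#' @param collection optional collection; cell types with zero scored
#'   signatures are reported as omitted with a warning.
#' @return data.frame with `cell_type`, `mean_nes`, `mean_p`,
#'   `n_signatures`, ordered by first appearance in `results`.
#' @export
aggregate_by_cell_type <- function(results, collection = NULL) {
  scored <- results[!is.na(results$nes), , drop = FALSE]
  if (!is.null(collection)) {
    missing_ct <- setdiff(collection_cell_types(collection), scored$cell_type)
    if (length(missing_ct)) {
      warning("cell type(s) with no scored signature omitted: ",
              paste(missing_ct, collapse = ", "), call. = FALSE)
    }
  }
  ct <- factor(scored$cell_type, levels = unique(scored$cell_type))
  out <- data.frame(
    cell_type = levels(ct),
    mean_nes = as.numeric(tapply(scored$nes, ct, mean)),
    mean_p = as.numeric(tapply(scored$p, ct, mean)),
    n_signatures = as.integer(tapply(scored$p, ct, length)),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}
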