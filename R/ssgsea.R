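# Single-sample enrichment scoring (ssGSEA) and group comparisons of the
# per-sample scores.

#' Single-sample enrichment scores (ssGSEA)
#'
#' Per sample, genes are ranked by descending expression (tied values get
#' average ranks). Walking the ranked list, the cumulative hit mass is
#' weighted by `rank_value^alpha`, normalized over the signature's genes,
#' and the miss mass grows by `1/(N - m)` per non-signature gene; the score
#' is the sum over all list positions of (cumulative hit - cumulative
#' miss). Scores depend only on within-sample ranks, so any strictly
#' increasing transform of one sample's expression leaves its scores
#' unchanged.
#'
#' @param mat numeric expression matrix, genes x samples.
#' @param collection a [signature_collection()], or a plain character
#'   vector / named list of gene vectors.
#' @param alpha rank-weight exponent (default 0.25).
#' @param min_overlap signatures with fewer genes present are skipped with
#'   a warning (default 5).
#' @return numeric matrix of scores, signatures x samples, with attribute
#'   `score_kind = "ssgsea_raw"`.
#' @export
ssgsea_score <- function(mat, collection, alpha = 0.25, min_overlap = 5) {
  sets <- if (inherits(collection, "SignatureCollection")) {
    collection$sets
  } else if (is.character(collection)) {
    list(signature = norm_gene_ids(collection))
  } else {
    lapply(collection, norm_gene_ids)
  }
  genes <- norm_gene_ids(rownames(mat))
  N <- length(genes)
  ov <- vapply(sets, function(g) sum(genes %in% g), integer(1L))
  skip <- ov < min_overlap | ov == N
  if (any(skip)) {
    warning("skipping ", sum(skip), " signature(s) with overlap < ",
            min_overlap, " (or full-universe overlap): ",
            paste(names(sets)[skip], collapse = ", "), call. = FALSE)
  }
  sets <- sets[!skip]
  if (!length(sets)) stop("no signature passes the overlap filter", call. = FALSE)
  members <- lapply(sets, function(g) genes %in% g)

  scores <- matrix(NA_real_, nrow = length(sets), ncol = ncol(mat),
                   dimnames = list(names(sets), colnames(mat)))
  for (j in seq_len(ncol(mat))) {
    xs <- mat[, j]
    ord <- order_desc_ties_by_name(xs, genes)
    rv <- rank(xs, ties.method = "average")[ord] # rank value, N at the top
    w <- rv^alpha
    for (k in seq_along(members)) {
      hit <- members[[k]][ord]
      m <- sum(hit)
      hit_inc <- ifelse(hit, w, 0)
      hit_cum <- cumsum(hit_inc) / sum(hit_inc)
      miss_cum <- cumsum(!hit) / (N - m)
      scores[k, j] <- sum(hit_cum - miss_cum)
    }
  }
  attr(scores, "score_kind") <- "ssgsea_raw"
  scores
}

#' Min-max rescale scores per row
#'
#' Per row (signature or cell type), maps scores linearly onto `[0, 1]`
#' over the dataset's samples; constant rows map to 0. Presentation
#' scaling only - within-row sample ordering is preserved.
#'
#' @param scores numeric matrix, rows x samples (>= 2 samples).
#' @return rescaled matrix with attribute `score_kind = "ssgsea_rescaled"`.
#' @export
rescale_scores <- function(scores) {
  if (ncol(scores) < 2L) stop("rescaling needs >= 2 samples", call. = FALSE)
  out <- t(apply(scores, 1L, function(r) {
    rng <- max(r) - min(r)
    if (rng == 0) rep(0, length(r)) else (r - min(r)) / rng
  }))
  dimnames(out) <- dimnames(scores)
  attr(out, "score_kind") <- "ssgsea_rescaled"
  out
}

#' Aggregate per-signature scores to cell-type scores
#'
#' A cell type's score in a sample is the mean of its signatures' scores in
#' that sample.
#'
#' @param scores numeric matrix, signatures x samples (rownames must be
#'   signature names of `collection`).
#' @param collection the [signature_collection()] defining the grouping.
#' @return numeric matrix, cell types x samples.
#' @export
aggregate_cell_type_scores <- function(scores, collection) {
  ct <- collection$cell_type[rownames(scores)]
  if (anyNA(ct)) {
    stop("score rows not in collection: ",
         paste(rownames(scores)[is.na(ct)], collapse = ", "), call. = FALSE)
  }
  f <- factor(ct, levels = unique(ct))
  out <- rowsum(scores, f) / as.vector(table(f)[levels(f)])
  out <- out[levels(f), , drop = FALSE]
  attr(out, "score_kind") <- attr(scores, "score_kind")
  out
}

#' Compare score distributions between sample groups
#'
#' Two-sided Mann-Whitney U test per score row and group pair: the exact
#' null distribution when the combined sample count is at most 12 and
#' there are no ties, otherwise the normal approximation with tie
#' correction. Stars follow the usual thresholds (`*` p < 0.05, `**`
#' p < 0.01). Groups with fewer than 3 samples are skipped with a warning.
#'
#' @param scores numeric matrix, rows x samples.
#' @param metadata data.frame with `sample_id` and the grouping column.
#' @param group_pairs list of length-2 character vectors of group labels;
#'   default: all unordered pairs of observed groups.
#' @param group_col metadata column holding the group label.
#' @return data.frame with `row_id`, `group_a`, `group_b`, `statistic`
#'   (the U statistic for `group_a`), `p_value`, `padj`
#'   (Benjamini-Hochberg within each pair), `star`.
#' @export
compare_groups <- function(scores, metadata, group_pairs = NULL,
                           group_col = "group") {
  metadata <- align_metadata(scores, metadata)
  groups <- unique(metadata[[group_col]])
  if (is.null(group_pairs)) {
    if (length(groups) < 2L) stop("need >= 2 groups to compare", call. = FALSE)
    group_pairs <- utils::combn(groups, 2L, simplify = FALSE)
  }
  res <- list()
  for (pair in group_pairs) {
    a <- metadata$sample_id[metadata[[group_col]] == pair[1L]]
    b <- metadata$sample_id[metadata[[group_col]] == pair[2L]]
    if (length(a) < 3L || length(b) < 3L) {
      warning("skipping comparison ", pair[1L], " vs ", pair[2L],
              ": group below 3 samples", call. = FALSE)
      next
    }
    stat <- p <- numeric(nrow(scores))
    for (i in seq_len(nrow(scores))) {
      xa <- scores[i, a]
      xb <- scores[i, b]
      exact <- (length(xa) + length(xb) <= 12L) &&
        !anyDuplicated(c(xa, xb))
      wt <- stats::wilcox.test(xa, xb, alternative = "two.sided",
                               exact = exact, correct = !exact)
      stat[i] <- unname(wt$statistic)
      p[i] <- wt$p.value
    }
    res[[length(res) + 1L]] <- data.frame(
      row_id = rownames(scores), group_a = pair[1L], group_b = pair[2L],
      statistic = stat, p_value = p,
      padj = stats::p.adjust(p, method = "BH"),
      star = p_stars(p),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(row_id = character(), group_a = character(),
                      group_b = character(), statistic = numeric(),
                      p_value = numeric(), padj = numeric(),
                      star = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}
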