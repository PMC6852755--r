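# Treatment-response prediction: median-signature scores, ROC/AUC via the
# rank (Mann-Whitney) identity, and per-cell-type AUC aggregation.

#' Median-signature prediction scores
#'
#' The prediction score of a signature in a sample is the median expression
#' of the signature's genes present in the matrix (even gene counts use the
#' mean of the two middle values). Signatures with zero overlap are skipped
#' with a warning.
#'
#' @param mat numeric expression matrix, genes x samples.
#' @param collection a [signature_collection()], or a plain character
#'   vector / named list of gene vectors.
#' @return numeric matrix of scores, signatures x samples, with attribute
#'   `score_kind = "median_expression"`.
#' @export
median_signature_score <- function(mat, collection) {
  sets <- if (inherits(collection, "SignatureCollection")) {
    collection$sets
  } else if (is.character(collection)) {
    list(signature = norm_gene_ids(collection))
  } else {
    lapply(collection, norm_gene_ids)
  }
  genes <- norm_gene_ids(rownames(mat))
  present <- lapply(sets, function(g) which(genes %in% g))
  empty <- lengths(present) == 0L
  if (any(empty)) {
    warning("skipping ", sum(empty), " signature(s) with zero overlap: ",
            paste(names(sets)[empty], collapse = ", "), call. = FALSE)
    present <- present[!empty]
  }
  if (!length(present)) stop("no signature overlaps the matrix", call. = FALSE)
  out <- t(vapply(present,
                  function(i) apply(mat[i, , drop = FALSE], 2L, stats::median),
                  numeric(ncol(mat))))
  dimnames(out) <- list(names(present), colnames(mat))
  attr(out, "score_kind") <- "median_expression"
  out
}

#' ROC curve and AUC for a score vector
#'
#' The AUC is computed through the rank/Mann-Whitney identity
#' `U / (n_pos * n_neg)` with tied scores contributing 1/2; higher scores
#' are oriented toward the positive class. The ROC point sequence walks all
#' distinct thresholds in descending order, from (0, 0) to (1, 1), and its
#' trapezoidal area equals the rank AUC.
#'
#' @param scores numeric vector of prediction scores.
#' @param labels vector of class labels, same length as `scores`.
#' @param positive the positive class label (e.g. the non-responder label;
#'   higher score = predicted positive).
#' @return object of class `RocResult`: list with `auc`, `points`
#'   (data.frame `threshold`, `fpr`, `tpr`), `positive`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  is_pos <- labels == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present (positive '", positive, "': ",
         n_pos, ", negative: ", n_neg, ")", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  u <- sum(r[is_pos]) - n_pos * (n_pos + 1) / 2
  auc <- u / (n_pos * n_neg)

  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores[is_pos] >= t) / n_pos, numeric(1L))
  fpr <- vapply(th, function(t) sum(scores[!is_pos] >= t) / n_neg, numeric(1L))
  points <- data.frame(threshold = c(Inf, th), fpr = c(0, fpr),
                       tpr = c(0, tpr), row.names = NULL)
  structure(list(auc = auc, points = points, positive = positive,
                 n_pos = n_pos, n_neg = n_neg),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("RocResult: AUC = %.4f (positive '%s', %d vs %d)\n",
              x$auc, x$positive, x$n_pos, x$n_neg))
  invisible(x)
}

#' Per-signature ROC/AUC over a score matrix
#'
#' Runs [roc_auc()] on every row of a prediction-score matrix against the
#' response labels of the annotated samples. Samples can optionally be
#' restricted to one timepoint first (pre- and post-treatment cohorts are
#' scored separately by default in the pipeline).
#'
#' @param scores numeric matrix, signatures x samples (e.g. from
#'   [median_signature_score()]).
#' @param metadata data.frame with `sample_id` and the response column.
#' @param positive positive class label (default `"NR"`, non-responder).
#' @param response_col metadata column holding the class label.
#' @param timepoint optional value of `metadata$timepoint` to subset on.
#' @return data.frame with `signature`, `auc`, `n_pos`, `n_neg`.
#' @export
signature_auc <- function(scores, metadata, positive = "NR",
                          response_col = "response", timepoint = NULL) {
  metadata <- align_metadata(scores, metadata)
  if (!is.null(timepoint)) {
    metadata <- metadata[!is.na(metadata$timepoint) &
                           metadata$timepoint == timepoint, , drop = FALSE]
  }
  metadata <- metadata[!is.na(metadata[[response_col]]) &
                         nzchar(metadata[[response_col]]), , drop = FALSE]
  ids <- metadata$sample_id
  labels <- metadata[[response_col]]
  auc <- vapply(rownames(scores), function(s) {
    roc_auc(scores[s, ids], labels, positive)$auc
  }, numeric(1L))
  data.frame(signature = rownames(scores), auc = unname(auc),
             n_pos = sum(labels == positive),
             n_neg = sum(labels != positive),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cell-type AUC table
#'
#' A cell type's AUC is the arithmetic mean of its signatures' AUCs. The
#' table is sorted by descending AUC (ties broken by cell-type name) with
#' an optional top-k view.
#'
#' @param sig_auc data.frame from [signature_auc()].
#' @param collection the [signature_collection()] mapping signatures to
#'   cell types.
#' @param top_k emit only the first `top_k` rows (default `Inf` = all).
#' @return data.frame with `cell_type`, `auc`, `n_signatures`, sorted
#'   descending by `auc`.
#' @export
cell_type_auc <- function(sig_auc, collection, top_k = Inf) {
  ct <- collection$cell_type[sig_auc$signature]
  if (anyNA(ct)) {
    stop("signature(s) not in collection: ",
         paste(sig_auc$signature[is.na(ct)], collapse = ", "), call. = FALSE)
  }
  f <- factor(ct, levels = unique(ct))
  out <- data.frame(
    cell_type = levels(f),
    auc = as.numeric(tapply(sig_auc$auc, f, mean)),
    n_signatures = as.integer(tapply(sig_auc$auc, f, length)),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$auc, out$cell_type, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}
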