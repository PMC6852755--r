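# Sample-wise standardization of expression matrices.

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto a common reference distribution: the
#' mean of the column-sorted value vectors. Within a sample, the value at
#' rank r is replaced by the r-th reference value; tied values receive the
#' mean of the reference values across their tied rank positions, so equal
#' inputs stay equal. Gene and sample ordering are preserved.
#'
#' @param mat numeric matrix, genes x samples, all values finite,
#'   >= 2 genes and >= 2 samples.
#' @return list with elements `matrix` (the normalized matrix) and `report`
#'   (a `NormalizationReport`: method, dimensions, per-sample min/median/max
#'   before and after).
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("mat must be a numeric matrix", call. = FALSE)
  }
  if (ncol(mat) < 2L) {
    stop("quantile normalization needs >= 2 samples", call. = FALSE)
  }
  if (nrow(mat) < 2L) {
    stop("quantile normalization needs >= 2 genes", call. = FALSE)
  }
  if (!all(is.finite(mat))) stop("all values must be finite", call. = FALSE)

  ref <- rowMeans(apply(mat, 2L, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    assigned <- numeric(length(col))
    assigned[order(col)] <- ref
    # tie groups (identical values) get the mean reference over their block
    out[, j] <- stats::ave(assigned, factor(col), FUN = mean)
  }

  summarize <- function(m) {
    data.frame(sample_id = colnames(m),
               min = apply(m, 2L, min),
               median = apply(m, 2L, stats::median),
               max = apply(m, 2L, max),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  report <- structure(
    list(method = "quantile", n_genes = nrow(mat), n_samples = ncol(mat),
         pre = summarize(mat), post = summarize(out)),
    class = "NormalizationReport")
  list(matrix = out, report = report)
}

#' @export
print.NormalizationReport <- function(x, ...) {
  cat(sprintf("NormalizationReport: %s, %d genes x %d samples\n",
              x$method, x$n_genes, x$n_samples))
  cat(sprintf("  post-normalization medians span [%.4g, %.4g]\n",
              min(x$post$median), max(x$post$median)))
  invisible(x)
}

#' Log2-transform a linear-scale expression matrix
#'
#' Elementwise `log2(value + offset)`. Intended for linear-intensity inputs;
#' matrices already on the log scale should skip this step.
#'
#' @param mat numeric matrix with non-negative values.
#' @param offset positive pseudo-count (default 1).
#' @return transformed matrix of the same shape.
#' @export
log2_transform <- function(mat, offset = 1) {
  if (any(mat < 0)) stop("negative values cannot be log2-transformed", call. = FALSE)
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0) {
    stop("offset must be a single positive number", call. = FALSE)
  }
  log2(mat + offset)
}
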