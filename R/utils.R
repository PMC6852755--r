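# Internal helpers shared across modules.

#' Canonical form of a gene identifier
#'
#' Gene symbols arriving from expression tables, GMT files and built-in
#' panels are matched case-insensitively after whitespace stripping, because
#' signature resources and array platforms mix symbol cases.
#'
#' @param x character vector of gene identifiers.
#' @return character vector in canonical (upper-case, trimmed) form.
#' @keywords internal
norm_gene_ids <- function(x) {
  toupper(trimws(as.character(x)))
}

# Row standard deviations of a numeric matrix (denominator n - 1).
row_sds <- function(m) {
  n <- ncol(m)
  if (n < 2L) {
    return(rep(0, nrow(m)))
  }
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1L))
}

#' Significance stars for p-values
#'
#' `"**"` for p < 0.01, `"*"` for 0.01 <= p < 0.05, `""` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of stars.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

# Deterministic order: primary key descending numeric, ties broken by
# identifier in C-locale lexicographic order.
order_desc_ties_by_name <- function(value, id) {
  order(-value, id, method = "radix")
}

# Match annotated samples against a matrix; errors when the intersection is
# empty, returns the annotation rows restricted to samples present.
align_metadata <- function(mat, metadata) {
  if (!"sample_id" %in% colnames(metadata)) {
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  }
  keep <- metadata$sample_id %in% colnames(mat)
  if (!any(keep)) {
    stop("no metadata sample_id matches a column of the expression matrix",
         call. = FALSE)
  }
  metadata[keep, , drop = FALSE]
}
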