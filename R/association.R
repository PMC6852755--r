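# Signature-signature and signature-panel association: Spearman correlation
# of median scores with common-gene removal, and marker-panel group medians.

#' Built-in marker gene panels
#'
#' Named gene panels used in the association analyses:
#' `proinflammatory` (IL1B, IL1A, IL23, IL12A, IL12B, TNFA, IL6, IL8, IL18,
#' IFNA1, IFNB1), `myeloid_chemokines` (CXCL1/2/3/5/6, CCL2/3/4/24,
#' chemokines involved in myeloid cell trafficking), `lymphocyte_chemokines`
#' (CXCL9/10/11/13, CCL18/22, Th1/Th2 response and migration) and
#' `il17_il22` (IL17A, IL22). Panel members are matched case-insensitively
#' against the expression matrix; absent genes are dropped at scoring time.
#'
#' @return named list of character vectors.
#' @export
builtin_panels <- function() {
  list(
    proinflammatory = c("IL1B", "IL1A", "IL23", "IL12A", "IL12B", "TNFA",
                        "IL6", "IL8", "IL18", "IFNA1", "IFNB1"),
    myeloid_chemokines = c("CXCL1", "CXCL2", "CXCL3", "CXCL5", "CXCL6",
                           "CCL2", "CCL3", "CCL4", "CCL24"),
    lymphocyte_chemokines = c("CXCL9", "CXCL10", "CXCL11", "CXCL13",
                              "CCL18", "CCL22"),
    il17_il22 = c("IL17A", "IL22")
  )
}

#' Per-sample panel score
#'
#' A panel's expression in a sample is the median over the panel genes
#' present in the matrix. Missing genes are dropped with a message; a panel
#' with zero overlap is an error naming the panel.
#'
#' @param mat numeric expression matrix, genes x samples.
#' @param panel character vector of gene symbols (or a name from
#'   [builtin_panels()]).
#' @param name label used in error messages (defaults to the panel name
#'   when a built-in is selected).
#' @return named numeric vector, one score per sample.
#' @export
panel_score <- function(mat, panel, name = NULL) {
  if (length(panel) == 1L && panel %in% names(builtin_panels())) {
    name <- panel
    panel <- builtin_panels()[[panel]]
  }
  if (is.null(name)) name <- "panel"
  panel <- unique(norm_gene_ids(panel))
  genes <- norm_gene_ids(rownames(mat))
  idx <- which(genes %in% panel)
  if (!length(idx)) {
    stop("panel '", name, "' has no gene in the matrix", call. = FALSE)
  }
  dropped <- setdiff(panel, genes)
  if (length(dropped)) {
    message("panel '", name, "': ", length(dropped),
            " gene(s) absent and dropped: ", paste(dropped, collapse = ", "))
  }
  apply(mat[idx, , drop = FALSE], 2L, stats::median)
}

# Symmetric common-gene removal: both members of a pair lose the shared
# genes before scoring, so the gene sets actually used are disjoint.
deoverlap_pair <- function(genes_a, genes_b) {
  shared <- intersect(genes_a, genes_b)
  list(a = setdiff(genes_a, shared), b = setdiff(genes_b, shared))
}

#' Pairwise Spearman correlation of signature/panel scores
#'
#' For every pair of gene sets (signatures of `collection` plus optional
#' named `panels`), genes shared by the two sets are removed from both,
#' each side is summarized as its per-sample median over the remaining
#' genes, and Spearman's rho (average ranks on ties) is computed over the
#' samples. Pairs whose de-overlapped sets have no genes left in the matrix
#' get a missing rho with a warning. Diagonal entries are 1 by convention
#' and flagged as self-correlations.
#'
#' @param mat numeric expression matrix with >= 4 samples.
#' @param collection a [signature_collection()] (may be `NULL` when only
#'   panels are correlated).
#' @param panels optional named list of gene vectors, e.g. from
#'   [builtin_panels()].
#' @return object of class `CorrelationMatrix`: list with `rho` (symmetric
#'   matrix, unit diagonal), `n_samples`, and `self` (logical matrix
#'   flagging the by-convention diagonal).
#' @export
pairwise_spearman <- function(mat, collection = NULL, panels = NULL) {
  if (ncol(mat) < 4L) stop("need >= 4 samples for correlation", call. = FALSE)
  sets <- list()
  if (!is.null(collection)) sets <- c(sets, collection$sets)
  if (!is.null(panels)) sets <- c(sets, lapply(panels, norm_gene_ids))
  if (length(sets) < 2L) stop("need >= 2 gene sets to correlate", call. = FALSE)
  if (anyDuplicated(names(sets))) {
    stop("signature and panel names must be unique", call. = FALSE)
  }
  n <- length(sets)
  genes <- norm_gene_ids(rownames(mat))
  rho <- matrix(NA_real_, n, n, dimnames = list(names(sets), names(sets)))
  diag(rho) <- 1
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      de <- deoverlap_pair(sets[[i]], sets[[j]])
      ga <- which(genes %in% de$a)
      gb <- which(genes %in% de$b)
      if (!length(ga) || !length(gb)) {
        warning("pair ", names(sets)[i], " / ", names(sets)[j],
                ": empty gene set after common-gene removal; rho missing",
                call. = FALSE)
        next
      }
      sa <- apply(mat[ga, , drop = FALSE], 2L, stats::median)
      sb <- apply(mat[gb, , drop = FALSE], 2L, stats::median)
      rho[i, j] <- rho[j, i] <- stats::cor(sa, sb, method = "spearman")
    }
  }
  self <- diag(TRUE, n)
  dimnames(self) <- dimnames(rho)
  structure(list(rho = rho, n_samples = ncol(mat), self = self),
            class = "CorrelationMatrix")
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat(sprintf("CorrelationMatrix: %d x %d gene sets over %d samples\n",
              nrow(x$rho), ncol(x$rho), x$n_samples))
  off <- x$rho[!x$self]
  if (length(off)) {
    cat(sprintf("  off-diagonal rho: [%.3f, %.3f]\n",
                min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  }
  invisible(x)
}

#' Group medians of a panel score, with pairwise tests
#'
#' Summarizes a marker panel per sample group: the group median of the
#' per-sample panel scores, plus pairwise Mann-Whitney comparisons with
#' significance stars (same conventions as [compare_groups()]). Groups
#' with fewer than 3 samples are skipped with a warning.
#'
#' @param mat numeric expression matrix.
#' @param metadata data.frame with `sample_id` and the grouping column.
#' @param panel character vector of gene symbols or a built-in panel name.
#' @param group_col metadata column holding the group label.
#' @return list with `medians` (data.frame `group`, `median_score`, `n`)
#'   and `tests` (data.frame from [compare_groups()] on the panel score).
#' @export
panel_group_medians <- function(mat, metadata, panel, group_col = "group") {
  name <- if (length(panel) == 1L) panel else "panel"
  score <- panel_score(mat, panel, name = name)
  metadata <- align_metadata(mat, metadata)
  groups <- unique(metadata[[group_col]])
  n_per <- vapply(groups, function(g)
    sum(metadata[[group_col]] == g), integer(1L))
  small <- n_per < 3L
  if (any(small)) {
    warning("skipping group(s) below 3 samples: ",
            paste(groups[small], collapse = ", "), call. = FALSE)
    groups <- groups[!small]
  }
  if (!length(groups)) stop("no group has >= 3 samples", call. = FALSE)
  med <- vapply(groups, function(g) {
    stats::median(score[metadata$sample_id[metadata[[group_col]] == g]])
  }, numeric(1L))
  medians <- data.frame(group = groups, median_score = unname(med),
                        n = unname(n_per[!small]),
                        row.names = NULL, stringsAsFactors = FALSE)
  score_mat <- matrix(score, nrow = 1L,
                      dimnames = list(name, names(score)))
  keep <- metadata[[group_col]] %in% groups
  tests <- compare_groups(score_mat, metadata[keep, , drop = FALSE],
                          group_col = group_col)
  list(medians = medians, tests = tests)
}
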