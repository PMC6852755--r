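# Readers and writers for expression matrices, sample metadata and GMT
# gene-set collections, plus the SignatureCollection container.

#' Read a genes-by-samples expression table
#'
#' Parses a tab- or comma-separated text file whose first column holds gene
#' identifiers and whose header row holds sample identifiers. Values are
#' expression intensities, assumed log2-scale after preprocessing.
#'
#' Gene identifiers are canonicalized (upper-cased, whitespace-stripped).
#' Duplicate gene rows are collapsed by taking, per sample, the maximum value
#' across the duplicates (the common probe-collapse convention). Rows whose
#' values are all missing are dropped; any other missing or non-numeric cell
#' is an error naming the offending gene and sample.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field separator; `NULL` (default) sniffs tab vs comma from the
#'   header line.
#' @return numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @export
read_expression <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("malformed header: expected a gene column plus >=1 sample column",
         call. = FALSE)
  }
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  genes <- norm_gene_ids(df[[1L]])
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  missing_tokens <- c("", "NA", "na", "NaN", "nan", "NULL")
  is_missing <- is.na(raw) | trimws(raw) %in% missing_tokens
  bad <- is.na(num) & !is_missing
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 raw[bad][1L], genes[idx[1L]], samples[idx[2L]]),
         call. = FALSE)
  }
  all_missing <- rowSums(!is.na(num)) == 0L
  num <- num[!all_missing, , drop = FALSE]
  genes <- genes[!all_missing]
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 genes[idx[1L]], samples[idx[2L]]), call. = FALSE)
  }
  if (!all(is.finite(num))) {
    idx <- which(!is.finite(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 genes[idx[1L]], samples[idx[2L]]), call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    groups <- split(seq_along(genes), factor(genes, levels = unique(genes)))
    num <- t(vapply(groups,
                    function(i) apply(num[i, , drop = FALSE], 2L, max),
                    numeric(ncol(num))))
    genes <- names(groups)
  }
  dimnames(num) <- list(genes, samples)
  num
}

#' Write an expression matrix to TSV
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat))) df[[colnames(mat)[j]]] <- mat[, j]
  write_table(df, path)
}

#' Read per-sample annotations
#'
#' Expects a TSV with a header and a `sample_id` column (group, response,
#' timepoint, location columns are carried through as character).
#'
#' @param path path to the metadata TSV.
#' @return data.frame with character columns and unique `sample_id`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) {
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Construct a signature collection
#'
#' A `SignatureCollection` groups named gene sets by the cell type each one
#' represents (e.g. several independently derived "Monocytes" signatures).
#'
#' @param sets named list of character vectors of gene symbols; names are
#'   signature names and must be unique, sets must be non-empty.
#' @param cell_types character vector of cell-type labels, one per signature
#'   (recycled names of `sets` order).
#' @return object of class `SignatureCollection` with elements `sets`
#'   (genes canonicalized and deduplicated) and `cell_type` (named character
#'   vector).
#' @export
signature_collection <- function(sets, cell_types) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every signature must be named", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate signature names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  }
  if (length(cell_types) != length(sets)) {
    stop("cell_types must have one entry per signature", call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(norm_gene_ids(g[nzchar(trimws(g))])))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    stop("empty gene set(s): ", paste(names(sets)[empty], collapse = ", "),
         call. = FALSE)
  }
  cell_type <- as.character(cell_types)
  names(cell_type) <- names(sets)
  structure(list(sets = sets, cell_type = cell_type),
            class = "SignatureCollection")
}

#' @export
print.SignatureCollection <- function(x, ...) {
  cat(sprintf("SignatureCollection: %d signatures, %d cell types\n",
              length(x$sets), length(unique(x$cell_type))))
  cat(sprintf("  gene-set sizes: %d-%d (median %.0f)\n",
              min(lengths(x$sets)), max(lengths(x$sets)),
              stats::median(lengths(x$sets))))
  invisible(x)
}

#' @export
length.SignatureCollection <- function(x) length(x$sets)

#' Cell types represented in a collection
#' @param collection a `SignatureCollection`.
#' @return character vector of distinct cell-type labels, in first-appearance
#'   order.
#' @export
collection_cell_types <- function(collection) {
  unique(unname(collection$cell_type))
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one signature per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The cell type of each
#' signature is taken from `cell_type_map` when supplied, otherwise parsed
#' from the signature name as the prefix before the first underscore (the
#' `CellType_source_N` convention of cell-type signature compendia).
#'
#' @param path path to the GMT file.
#' @param cell_type_map optional: either a named character vector
#'   (signature name -> cell type) or the path of a two-column TSV with
#'   columns `signature` and `cell_type`.
#' @return a [signature_collection()].
#' @export
read_gmt <- function(path, cell_type_map = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short)) {
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields",
                 line_no[which(short)[1L]]), call. = FALSE)
  }
  nm <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate signature names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nm
  if (is.null(cell_type_map)) {
    ct <- sub("_.*$", "", nm)
  } else {
    if (is.character(cell_type_map) && length(cell_type_map) == 1L &&
        is.null(names(cell_type_map)) && file.exists(cell_type_map)) {
      map_df <- utils::read.table(cell_type_map, sep = "\t", header = TRUE,
                                  colClasses = "character", quote = "",
                                  stringsAsFactors = FALSE)
      if (!all(c("signature", "cell_type") %in% colnames(map_df))) {
        stop("cell-type map file needs columns 'signature' and 'cell_type'",
             call. = FALSE)
      }
      cell_type_map <- stats::setNames(map_df$cell_type, map_df$signature)
    }
    missing_map <- setdiff(nm, names(cell_type_map))
    if (length(missing_map)) {
      stop("cell_type_map lacks entries for: ",
           paste(missing_map, collapse = ", "), call. = FALSE)
    }
    ct <- unname(cell_type_map[nm])
  }
  signature_collection(sets, ct)
}

#' Write a signature collection to GMT
#'
#' The description field records the cell type, so a round trip through
#' [read_gmt()] with the collection's own map reproduces the object.
#'
#' @param collection a `SignatureCollection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$cell_type[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Filter a signature collection by gene count and cell type
#'
#' Applies the resource-level filter used to assemble an analysis-ready
#' compendium: signatures with fewer than `min_genes` members are dropped,
#' as are all signatures of the cell types in `drop_cell_types` (defaults
#' drop the immature-DC and NKT groups, whose published signatures are too
#' small to score stably).
#'
#' @param collection a `SignatureCollection`.
#' @param min_genes minimum gene count per signature (default 15).
#' @param drop_cell_types character vector of cell-type labels to remove.
#' @return the filtered `SignatureCollection`.
#' @export
filter_signatures <- function(collection, min_genes = 15,
                              drop_cell_types = c("iDC", "NKT")) {
  keep <- lengths(collection$sets) >= min_genes &
    !(collection$cell_type %in% drop_cell_types)
  if (!any(keep)) stop("no signatures pass the filter", call. = FALSE)
  signature_collection(collection$sets[keep], collection$cell_type[keep])
}

#' Write a tabular result to TSV
#'
#' Columns are written in their existing (deterministic) order; numeric
#' columns are serialized with 15 significant digits so a read-back
#' reproduces values to well within 1e-12 relative error.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.15g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a TSV written by [write_table()]
#'
#' @param path path to the TSV.
#' @return data.frame with numeric columns restored.
#' @export
read_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    quote = "", comment.char = "", stringsAsFactors = FALSE)
}
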