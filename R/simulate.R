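# Synthetic bulk-mixture generator: cohorts of bulk expression profiles
# built as noisy convex mixtures of cell-type archetypes with known
# fractions, so every pipeline stage can be validated by parameter
# recovery.

#' Simulation configuration
#'
#' Defines a synthetic bulk cohort. Each cell type owns
#' `signatures_per_type` disjoint marker signatures of `signature_size`
#' genes; the cell type's archetype elevates the union of its signature
#' genes by `delta` log2 units over a `N(baseline_mean, baseline_sd)`
#' background. Per sample, cell-type fractions are drawn from a
#' group-specific Dirichlet: every type has concentration
#' `dirichlet_alpha`, and the types named in `shift` get their
#' concentration multiplied in that group, shifting their mean fraction
#' upward. A bulk sample mixes the archetypes on the linear scale
#' (expression adds in transcript space), is log2-transformed, and gets
#' additive Gaussian noise of sd `noise_sd`.
#'
#' @param n_genes total gene count (default 2000).
#' @param cell_types character vector of cell-type names (default: 8 immune
#'   cell types with Monocytes first).
#' @param signatures_per_type signatures per cell type (default 2).
#' @param signature_size genes per signature (default 30).
#' @param baseline_mean,baseline_sd log2-scale background expression
#'   (defaults 6 and 1).
#' @param delta log2 elevation of a cell type's own signature genes in its
#'   archetype (default 2).
#' @param group_sizes named integer vector: samples per group, >= 2 each
#'   (default `c(inflamed = 20, non_inflamed = 20)`).
#' @param dirichlet_alpha base Dirichlet concentration per cell type
#'   (default 2).
#' @param shift named list: `group` -> named numeric vector of
#'   concentration multipliers per cell type (default: Monocytes x4 in the
#'   first group). Use an empty list for a null cohort.
#' @param noise_sd post-log additive Gaussian noise sd (default 0.5).
#' @param response_map optional named character vector mapping group label
#'   -> response label (e.g. `c(inflamed = "NR", non_inflamed = "R")`),
#'   stored in the metadata `response` column.
#' @param seed mandatory integer seed.
#' @return object of class `SimulationConfig` (a validated list).
#' @export
simulation_config <- function(n_genes = 2000,
                              cell_types = c("Monocytes", "Macrophages.M1",
                                             "Macrophages.M2", "aDC", "pDC",
                                             "CD4.T.cells", "CD8.T.cells",
                                             "B.cells"),
                              signatures_per_type = 2,
                              signature_size = 30,
                              baseline_mean = 6, baseline_sd = 1,
                              delta = 2,
                              group_sizes = c(inflamed = 20,
                                              non_inflamed = 20),
                              dirichlet_alpha = 2,
                              shift = list(inflamed = c(Monocytes = 4)),
                              noise_sd = 0.5,
                              response_map = NULL,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (anyDuplicated(cell_types)) stop("cell_types must be unique", call. = FALSE)
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    stop("group_sizes must be named", call. = FALSE)
  }
  if (any(group_sizes < 2L)) stop("each group needs >= 2 samples", call. = FALSE)
  n_marker <- length(cell_types) * signatures_per_type * signature_size
  if (n_marker > n_genes) {
    stop("signature genes (", n_marker, ") exceed n_genes (", n_genes, ")",
         call. = FALSE)
  }
  if (dirichlet_alpha <= 0) stop("dirichlet_alpha must be > 0", call. = FALSE)
  for (g in names(shift)) {
    if (!g %in% names(group_sizes)) {
      stop("shift refers to unknown group '", g, "'", call. = FALSE)
    }
    bad <- setdiff(names(shift[[g]]), cell_types)
    if (length(bad)) {
      stop("shift refers to unknown cell type(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(shift[[g]] <= 0)) stop("shift multipliers must be > 0", call. = FALSE)
  }
  if (!is.null(response_map)) {
    bad <- setdiff(names(response_map), names(group_sizes))
    if (length(bad)) {
      stop("response_map refers to unknown group(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(n_genes = as.integer(n_genes), cell_types = cell_types,
                 signatures_per_type = as.integer(signatures_per_type),
                 signature_size = as.integer(signature_size),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 delta = delta, group_sizes = group_sizes,
                 dirichlet_alpha = dirichlet_alpha, shift = shift,
                 noise_sd = noise_sd, response_map = response_map,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# One Dirichlet draw via normalized gamma variates.
.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Simulate a bulk cohort with known cell-type fractions
#'
#' See [simulation_config()] for the generative model. Fully reproducible:
#' the same config (including seed) yields a bit-identical dataset.
#'
#' @param config a `SimulationConfig`.
#' @return object of class `SimulatedDataset`: list with `expression`
#'   (genes x samples log2 matrix), `metadata` (sample_id, group, response,
#'   timepoint), `signatures` (the true [signature_collection()]),
#'   `fractions` (samples x cell-types matrix of true mixing fractions,
#'   rows summing to 1) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  K <- length(config$cell_types)
  genes <- sprintf("G%05d", seq_len(config$n_genes))

  # disjoint signature gene blocks at the head of the gene list
  sig_names <- character(0)
  sig_ct <- character(0)
  sets <- list()
  pos <- 0L
  for (k in seq_len(K)) {
    for (s in seq_len(config$signatures_per_type)) {
      nm <- sprintf("%s_sig%d", config$cell_types[k], s)
      sets[[nm]] <- genes[pos + seq_len(config$signature_size)]
      pos <- pos + config$signature_size
      sig_names <- c(sig_names, nm)
      sig_ct <- c(sig_ct, config$cell_types[k])
    }
  }
  signatures <- signature_collection(sets, sig_ct)

  # archetype profiles: background draws, own signature genes elevated
  archetypes <- matrix(stats::rnorm(config$n_genes * K,
                                    mean = config$baseline_mean,
                                    sd = config$baseline_sd),
                       nrow = config$n_genes, ncol = K,
                       dimnames = list(genes, config$cell_types))
  for (k in seq_len(K)) {
    own <- unique(unlist(sets[sig_ct == config$cell_types[k]],
                         use.names = FALSE))
    archetypes[own, k] <- archetypes[own, k] + config$delta
  }
  lin <- 2^archetypes

  n_total <- sum(config$group_sizes)
  sample_ids <- sprintf("S%03d", seq_len(n_total))
  group <- rep(names(config$group_sizes), config$group_sizes)
  fractions <- matrix(NA_real_, nrow = n_total, ncol = K,
                      dimnames = list(sample_ids, config$cell_types))
  expr <- matrix(NA_real_, nrow = config$n_genes, ncol = n_total,
                 dimnames = list(genes, sample_ids))
  for (i in seq_len(n_total)) {
    alpha <- rep(config$dirichlet_alpha, K)
    names(alpha) <- config$cell_types
    mult <- config$shift[[group[i]]]
    if (!is.null(mult)) alpha[names(mult)] <- alpha[names(mult)] * mult
    f <- .rdirichlet(alpha)
    fractions[i, ] <- f
    bulk <- log2(as.vector(lin %*% f))
    if (config$noise_sd > 0) {
      bulk <- bulk + stats::rnorm(config$n_genes, sd = config$noise_sd)
    }
    expr[, i] <- bulk
  }

  response <- rep(NA_character_, n_total)
  if (!is.null(config$response_map)) {
    mapped <- group %in% names(config$response_map)
    response[mapped] <- unname(config$response_map[group[mapped]])
  }
  metadata <- data.frame(sample_id = sample_ids, group = group,
                         response = response,
                         timepoint = NA_character_,
                         row.names = NULL, stringsAsFactors = FALSE)
  structure(list(expression = expr, metadata = metadata,
                 signatures = signatures, fractions = fractions,
                 config = config),
            class = "SimulatedDataset")
}

#' @export
print.SimulatedDataset <- function(x, ...) {
  cat(sprintf("SimulatedDataset: %d genes x %d samples, %d cell types (%d signatures)\n",
              nrow(x$expression), ncol(x$expression),
              ncol(x$fractions), length(x$signatures$sets)))
  cat("  groups:", paste(sprintf("%s=%d", names(x$config$group_sizes),
                                 x$config$group_sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Inject gene overlap between two signatures
#'
#' Replaces `k` genes of the second signature with the first `k` genes of
#' the first signature, creating known shared genes (the expression matrix
#' is untouched; only the signature definitions change). Used to exercise
#' the common-gene-removal rule of [pairwise_spearman()].
#'
#' @param dataset a `SimulatedDataset`.
#' @param pair length-2 character vector of signature names.
#' @param k number of genes to share; must satisfy
#'   `k <= min(signature sizes) - 5`.
#' @return the modified `SimulatedDataset`.
#' @export
overlap_injection <- function(dataset, pair, k) {
  stopifnot(inherits(dataset, "SimulatedDataset"), length(pair) == 2L)
  sets <- dataset$signatures$sets
  if (!all(pair %in% names(sets))) {
    stop("unknown signature(s): ",
         paste(setdiff(pair, names(sets)), collapse = ", "), call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 0L) stop("k must be >= 0", call. = FALSE)
  max_k <- min(lengths(sets[pair])) - 5L
  if (k > max_k) {
    stop("k too large: at most ", max_k, " genes can be shared", call. = FALSE)
  }
  if (k == 0L) return(dataset)
  shared <- sets[[pair[1L]]][seq_len(k)]
  b <- sets[[pair[2L]]]
  b_own <- setdiff(b, shared)
  sets[[pair[2L]]] <- c(b_own[seq_len(length(b) - k)], shared)
  dataset$signatures <- signature_collection(sets,
                                             dataset$signatures$cell_type)
  dataset
}

#' Write a simulated dataset to a directory
#'
#' Emits `expression.tsv`, `metadata.tsv`, `signatures.gmt` and
#' `true_fractions.tsv`.
#'
#' @param dataset a `SimulatedDataset`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_simulated_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "SimulatedDataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(dataset$expression, file.path(out_dir, "expression.tsv"))
  write_table(dataset$metadata, file.path(out_dir, "metadata.tsv"))
  write_gmt(dataset$signatures, file.path(out_dir, "signatures.gmt"))
  fr <- data.frame(sample_id = rownames(dataset$fractions),
                   dataset$fractions, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(fr, file.path(out_dir, "true_fractions.tsv"))
  invisible(out_dir)
}
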