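# Orchestration: run the full analysis (normalize -> gsea / ssgsea ->
# predict -> correlate) from a single config, writing TSV outputs and a
# JSON manifest.

.pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

.validate_run_config <- function(config) {
  stochastic <- !is.null(config$simulate) || !is.null(config$gsea)
  if (stochastic && is.null(config$seed)) {
    stop("config must set 'seed' when a stochastic stage (simulate/gsea) is enabled",
         call. = FALSE)
  }
  if (is.null(config$simulate)) {
    for (f in c("expression", "metadata")) {
      if (is.null(config[[f]])) {
        stop("config needs '", f, "' (or a 'simulate' block)", call. = FALSE)
      }
      if (!file.exists(config[[f]])) {
        stop("config file not found: ", config[[f]], call. = FALSE)
      }
    }
    if (is.null(config$gmt)) stop("config needs 'gmt'", call. = FALSE)
    if (!file.exists(config$gmt)) {
      stop("config file not found: ", config$gmt, call. = FALSE)
    }
  }
  invisible(config)
}

#' Run the full enrichment pipeline from a config
#'
#' Stages run in dependency order; each is enabled by the presence of its
#' config block. Either a `simulate` block (arguments to
#' [simulation_config()]) or `expression` / `metadata` / `gmt` paths
#' provide the inputs. Optional blocks: `normalize` (logical; quantile
#' normalization, applied once per dataset before any stratification),
#' `gsea` (`group_a`, `group_b`, optional `group_col`, `n_perm`, `metric`,
#' `min_overlap`), `ssgsea` (optional `alpha`; adds cell-type scores and
#' group comparisons), `predict` (optional `positive`, `response_col`,
#' `timepoint`), `correlate` (optional `panels`: names from
#' [builtin_panels()]). A `stratify_by` metadata column splits every
#' downstream stage per stratum (subdirectories of `out_dir`). All outputs
#' are TSV plus a JSON manifest recording the config, its hash and the
#' seed; identical config and seed reproduce identical outputs.
#'
#' @param config named list, or path to a YAML file with the same
#'   structure.
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the in-memory results per stratum and
#'   the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  .validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    dataset <- .pipeline_stage("simulate", {
      args <- config$simulate
      args$seed <- config$seed
      sim <- simulate_cohort(do.call(simulation_config, args))
      write_simulated_dataset(sim, file.path(out_dir, "simulated"))
      sim
    })
    mat <- dataset$expression
    metadata <- dataset$metadata
    collection <- dataset$signatures
  } else {
    mat <- .pipeline_stage("read_expression", read_expression(config$expression))
    metadata <- .pipeline_stage("read_metadata", read_sample_metadata(config$metadata))
    collection <- .pipeline_stage("read_gmt",
                                  read_gmt(config$gmt, config$cell_type_map))
  }

  if (isTRUE(config$normalize)) {
    qn <- .pipeline_stage("normalize", quantile_normalize(mat))
    mat <- qn$matrix
    write_table(qn$report$post, file.path(out_dir, "normalization_post.tsv"))
  }

  strata <- list(. = metadata$sample_id)
  if (!is.null(config$stratify_by)) {
    col <- config$stratify_by
    if (!col %in% colnames(metadata)) {
      stop("stratify_by column '", col, "' not in metadata", call. = FALSE)
    }
    strata <- split(metadata$sample_id, metadata[[col]])
  }

  results <- list()
  for (stratum in names(strata)) {
    sdir <- if (stratum == ".") out_dir else file.path(out_dir, stratum)
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    ids <- intersect(strata[[stratum]], colnames(mat))
    smat <- mat[, ids, drop = FALSE]
    smeta <- metadata[metadata$sample_id %in% ids, , drop = FALSE]
    res <- list()

    if (!is.null(config$gsea)) {
      res$gsea <- .pipeline_stage("gsea", {
        g <- config$gsea
        out <- gsea(smat, smeta, collection,
                    group_a = g$group_a, group_b = g$group_b,
                    group_col = g$group_col %||% "group",
                    metric = g$metric %||% "s2n",
                    n_perm = g$n_perm %||% 1000,
                    seed = config$seed,
                    min_overlap = g$min_overlap %||% 5)
        write_table(out, file.path(sdir, "gsea_signatures.tsv"))
        write_table(aggregate_by_cell_type(out, collection),
                    file.path(sdir, "gsea_cell_types.tsv"))
        out
      })
    }

    if (!is.null(config$ssgsea)) {
      res$ssgsea <- .pipeline_stage("ssgsea", {
        alpha <- config$ssgsea$alpha %||% 0.25
        sc <- ssgsea_score(smat, collection, alpha = alpha)
        ct <- aggregate_cell_type_scores(sc, collection)
        write_table(data.frame(signature = rownames(sc), sc,
                               check.names = FALSE),
                    file.path(sdir, "ssgsea_signatures.tsv"))
        write_table(data.frame(cell_type = rownames(ct), ct,
                               check.names = FALSE),
                    file.path(sdir, "ssgsea_cell_types.tsv"))
        cmp <- compare_groups(ct, smeta,
                              group_col = config$ssgsea$group_col %||% "group")
        write_table(cmp, file.path(sdir, "group_comparisons.tsv"))
        list(signature_scores = sc, cell_type_scores = ct, comparisons = cmp)
      })
    }

    if (!is.null(config$predict)) {
      res$predict <- .pipeline_stage("predict", {
        p <- config$predict
        ms <- median_signature_score(smat, collection)
        sa <- signature_auc(ms, smeta,
                            positive = p$positive %||% "NR",
                            response_col = p$response_col %||% "response",
                            timepoint = p$timepoint)
        ca <- cell_type_auc(sa, collection, top_k = p$top_k %||% Inf)
        write_table(sa, file.path(sdir, "auc_signatures.tsv"))
        write_table(ca, file.path(sdir, "auc_cell_types.tsv"))
        list(scores = ms, signature_auc = sa, cell_type_auc = ca)
      })
    }

    if (!is.null(config$correlate)) {
      res$correlate <- .pipeline_stage("correlate", {
        panel_names <- config$correlate$panels
        panels <- if (is.null(panel_names)) NULL else
          builtin_panels()[panel_names]
        cm <- pairwise_spearman(smat, collection, panels = panels)
        write_table(data.frame(id = rownames(cm$rho), cm$rho,
                               check.names = FALSE),
                    file.path(sdir, "correlation_rho.tsv"))
        cm
      })
    }
    results[[stratum]] <- res
  }

  cfg_path <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(package = "immunoscope",
                   version = as.character(utils::packageVersion("immunoscope")),
                   seed = config$seed,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   strata = names(strata))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(results = results, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
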