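test_that("config validation catches invariant violations before generation", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(n_genes = 100, seed = 1), "exceed")
  expect_error(simulation_config(delta = -1, seed = 1), "delta")
  expect_error(simulation_config(group_sizes = c(A = 1, B = 5), seed = 1),
               ">= 2 samples")
  expect_error(simulation_config(shift = list(Z = c(Monocytes = 2)), seed = 1),
               "unknown group")
  expect_error(simulation_config(shift = list(inflamed = c(Nope = 2)), seed = 1),
               "unknown cell type")
})

test_that("simulation is deterministic and respects the mixture contract", {
  cfg <- simulation_config(n_genes = 400,
                           cell_types = c("Mono", "DC", "B"),
                           group_sizes = c(A = 4, B = 4),
                           shift = list(A = c(Mono = 3)), seed = 5)
  d1 <- simulate_cohort(cfg)
  d2 <- simulate_cohort(cfg)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$fractions, d2$fractions)
  # fractions live on the simplex
  expect_equal(unname(rowSums(d1$fractions)), rep(1, 8), tolerance = 1e-12)
  expect_true(all(d1$fractions >= 0))
  # signature genes disjoint across cell types by default
  genes_by_ct <- lapply(unique(d1$signatures$cell_type), function(ct) {
    unlist(d1$signatures$sets[d1$signatures$cell_type == ct], use.names = FALSE)
  })
  expect_length(intersect(genes_by_ct[[1]], genes_by_ct[[2]]), 0)
  expect_length(intersect(genes_by_ct[[1]], genes_by_ct[[3]]), 0)
  # metadata aligned with the matrix
  expect_equal(d1$metadata$sample_id, colnames(d1$expression))
  expect_equal(table(d1$metadata$group)[["A"]], 4L)
})

test_that("noise-free near-pure samples put their own signature genes on top", {
  # one dominant cell type per sample (huge concentration multiplier), no
  # noise, tight baseline: the top-expressed genes must be the dominant
  # type's signature genes exactly
  cfg <- simulation_config(n_genes = 200,
                           cell_types = c("Mono", "DC"),
                           signatures_per_type = 1, signature_size = 20,
                           baseline_sd = 0.1, delta = 4,
                           group_sizes = c(mono = 3, dc = 3),
                           shift = list(mono = c(Mono = 1e6),
                                        dc = c(DC = 1e6)),
                           noise_sd = 0, seed = 7)
  ds <- simulate_cohort(cfg)
  for (i in seq_len(ncol(ds$expression))) {
    dom <- ds$metadata$group[i]
    own <- ds$signatures$sets[[if (dom == "mono") "Mono_sig1" else "DC_sig1"]]
    top <- rownames(ds$expression)[order(-ds$expression[, i])][1:20]
    expect_setequal(top, own)
  }
})

test_that("response labels map through to the metadata", {
  cfg <- simulation_config(n_genes = 500, cell_types = c("Mono", "DC"),
                           group_sizes = c(NR = 3, R = 3),
                           shift = list(NR = c(Mono = 4)),
                           response_map = c(NR = "NR", R = "R"), seed = 9)
  ds <- simulate_cohort(cfg)
  expect_equal(ds$metadata$response, ds$metadata$group)
})

test_that("overlap injection shares exactly k genes and validates k", {
  ds <- simulate_cohort(simulation_config(
    n_genes = 500, cell_types = c("Mono", "DC"),
    group_sizes = c(A = 3, B = 3), shift = list(), seed = 11))
  expect_identical(overlap_injection(ds, c("Mono_sig1", "DC_sig1"), 0), ds)
  ds2 <- overlap_injection(ds, c("Mono_sig1", "DC_sig1"), 7)
  shared <- intersect(ds2$signatures$sets$Mono_sig1,
                      ds2$signatures$sets$DC_sig1)
  expect_length(shared, 7)
  expect_length(ds2$signatures$sets$DC_sig1,
                length(ds$signatures$sets$DC_sig1))
  expect_error(overlap_injection(ds, c("Mono_sig1", "DC_sig1"), 26),
               "too large")
  expect_error(overlap_injection(ds, c("Mono_sig1", "Nope"), 2), "unknown")
})

test_that("stronger fraction shifts yield larger mean enrichment", {
  mean_nes <- vapply(c(1, 2, 4), function(mult) {
    cfg <- simulation_config(n_genes = 500,
                             cell_types = c("Monocytes", "aDC", "pDC", "B.cells"),
                             group_sizes = c(A = 10, B = 10),
                             shift = if (mult == 1) list() else
                               list(A = c(Monocytes = mult)),
                             seed = 13)
    ds <- simulate_cohort(cfg)
    res <- suppressWarnings(gsea(ds$expression, ds$metadata, ds$signatures,
                                 "A", "B", n_perm = 200, seed = 13))
    agg <- aggregate_by_cell_type(res)
    agg$mean_nes[agg$cell_type == "Monocytes"]
  }, numeric(1))
  expect_true(all(diff(mean_nes) > 0))
})

test_that("simulated datasets round-trip through the writers", {
  ds <- simulate_cohort(simulation_config(
    n_genes = 300, cell_types = c("Mono", "DC"),
    group_sizes = c(A = 3, B = 3), shift = list(), seed = 17))
  dir <- withr::local_tempdir()
  write_simulated_dataset(ds, dir)
  expect_equal(read_expression(file.path(dir, "expression.tsv")),
               ds$expression, tolerance = 1e-12)
  meta <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(meta$sample_id, ds$metadata$sample_id)
  fr <- read_table(file.path(dir, "true_fractions.tsv"))
  expect_equal(as.matrix(fr[, -1]), ds$fractions, tolerance = 1e-12,
               ignore_attr = TRUE)
  col <- read_gmt(file.path(dir, "signatures.gmt"),
                  cell_type_map = stats::setNames(
                    ds$signatures$cell_type, names(ds$signatures$sets)))
  expect_equal(col$sets, ds$signatures$sets)
})
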