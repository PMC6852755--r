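test_that("signal-to-noise ranking matches elementwise arithmetic and orders genes", {
  mat <- toy_matrix(5, 4, seed = 3)
  meta <- toy_metadata(mat, c("A", "A", "B", "B"))
  ranked <- rank_genes(mat, meta, "A", "B")
  expected <- oracle_s2n(mat, c("S01", "S02"), c("S03", "S04"))
  expect_equal(ranked, expected[names(ranked)], tolerance = 1e-12)
  expect_true(all(diff(ranked) <= 0))

  # a gene uniformly higher in group A tops the list with a positive metric
  flat <- matrix(5, nrow = 4, ncol = 4,
                 dimnames = list(paste0("g", 1:4), colnames(mat)))
  flat["g3", ] <- c(9.0, 9.1, 5.0, 5.1)
  ranked_flat <- rank_genes(flat, meta, "A", "B")
  expect_equal(names(ranked_flat)[1], "G3")
  expect_gt(ranked_flat[1], 0)
})

test_that("swapping group labels negates the metric and reverses the order", {
  mat <- toy_matrix(12, 6, seed = 9)
  meta <- toy_metadata(mat, c("A", "A", "A", "B", "B", "B"))
  ab <- rank_genes(mat, meta, "A", "B")
  ba <- rank_genes(mat, meta, "B", "A")
  expect_equal(ab[sort(names(ab))], -ba[sort(names(ba))], tolerance = 1e-12)
  expect_equal(names(ba), rev(names(ab)))
})

test_that("rank_genes rejects undersized or mismatched inputs", {
  mat <- toy_matrix(5, 4)
  meta <- toy_metadata(mat, c("A", "B", "B", "B"))
  expect_error(rank_genes(mat, meta, "A", "B"), ">= 2 samples")
  meta2 <- data.frame(sample_id = c("x", "y"), group = c("A", "B"))
  expect_error(rank_genes(mat, meta2, "A", "B"), "no metadata sample_id")
})

test_that("enrichment score follows the weighted-KS walk", {
  stats <- c(a = 2.0, b = 1.5, c = 0.7, d = -0.5, e = -1.8)
  # signature = top-ranked gene only: hit mass reaches 1 at position 1
  expect_equal(enrichment_score(stats, "a")$es, 1.0)
  # standard convention: a bottom-only signature drives the running sum to
  # -1 just before the hit (mirror of the top-gene case)
  es_bot <- enrichment_score(stats, "e")
  expect_equal(es_bot$es, -1.0)
  expect_equal(es_bot$es, oracle_es(stats, "e"))
  expect_error(enrichment_score(stats, names(stats)), "empty complement")
  expect_error(enrichment_score(stats, "zzz"), "no overlap")
})

test_that("enrichment score matches the brute-force oracle on random cases", {
  set.seed(21)
  for (rep in 1:25) {
    N <- sample(5:40, 1)
    stats <- sort(rnorm(N), decreasing = TRUE)
    names(stats) <- sprintf("G%03d", sample(N))
    m <- sample(1:(N - 1), 1)
    sig <- sample(names(stats), m)
    for (w in c(0, 1, 1.5)) {
      es <- enrichment_score(stats, sig, weight = w)
      expect_equal(es$es, oracle_es(stats, sig, w), tolerance = 1e-12)
      expect_lte(abs(es$es), 1 + 1e-12)
      expect_equal(length(es$profile), N)
    }
  }
})

test_that("with weight 0 the score depends only on rank positions", {
  set.seed(5)
  stats1 <- sort(rnorm(12), decreasing = TRUE)
  stats2 <- sort(rexp(12), decreasing = TRUE) # same order, different values
  names(stats1) <- names(stats2) <- sprintf("G%02d", 1:12)
  sig <- c("G02", "G07", "G11")
  expect_equal(enrichment_score(stats1, sig, weight = 0)$es,
               enrichment_score(stats2, sig, weight = 0)$es,
               tolerance = 1e-12)
})

test_that("enrichment score agrees with fgsea's statistic", {
  set.seed(17)
  for (rep in 1:10) {
    N <- 50
    stats <- sort(rnorm(N), decreasing = TRUE)
    names(stats) <- sprintf("G%03d", 1:N)
    sig <- sample(names(stats), 8)
    ours <- enrichment_score(stats, sig, weight = 1)$es
    theirs <- fgsea::calcGseaStat(stats, which(names(stats) %in% sig),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})

test_that("exhaustive 3v3 permutation p equals full enumeration", {
  set.seed(31)
  mat <- toy_matrix(30, 6, seed = 31)
  meta <- toy_metadata(mat, c("A", "A", "A", "B", "B", "B"))
  sig <- rownames(mat)[c(1, 4, 9, 12, 20)]
  col <- signature_collection(list(sig1 = sig), "ct")
  res <- suppressWarnings(
    gsea(mat, meta, col, "A", "B", n_perm = 100, seed = 1))
  oracle <- oracle_exhaustive_gsea(mat, colnames(mat)[1:3],
                                   colnames(mat)[4:6], sig)
  expect_equal(res$n_perm, choose(6, 3))
  expect_equal(res$es, oracle$es, tolerance = 1e-12)
  expect_equal(res$nes, oracle$nes, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
})

test_that("label swap negates ES and NES and keeps p (exhaustive null)", {
  mat <- toy_matrix(40, 6, seed = 13)
  meta <- toy_metadata(mat, c("A", "A", "A", "B", "B", "B"))
  col <- signature_collection(list(s = rownames(mat)[c(2, 5, 11, 17, 23)]),
                              "ct")
  ab <- suppressWarnings(gsea(mat, meta, col, "A", "B", n_perm = 100, seed = 2))
  ba <- suppressWarnings(gsea(mat, meta, col, "B", "A", n_perm = 100, seed = 2))
  expect_equal(ab$es, -ba$es, tolerance = 1e-12)
  expect_equal(ab$nes, -ba$nes, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
})

test_that("gsea output satisfies its invariants on a synthetic cohort", {
  ds <- simulate_cohort(simulation_config(
    n_genes = 400, cell_types = c("Monocytes", "aDC", "B.cells"),
    group_sizes = c(inflamed = 8, non_inflamed = 8),
    shift = list(inflamed = c(Monocytes = 4)), seed = 41))
  res <- suppressWarnings(
    gsea(ds$expression, ds$metadata, ds$signatures, "inflamed",
         "non_inflamed", n_perm = 200, seed = 41))
  expect_true(all(abs(res$es) <= 1 + 1e-12))
  expect_true(all(res$p >= 1 / (res$n_perm + 1) - 1e-12))
  nz <- res$es != 0 & !is.na(res$nes)
  expect_true(all(sign(res$nes[nz]) == sign(res$es[nz])))
  expect_true(all(res$n_genes_used >= 5))
})

test_that("signatures below the overlap floor are skipped with a warning", {
  mat <- toy_matrix(30, 14, seed = 2)
  meta <- toy_metadata(mat, rep(c("A", "B"), each = 7))
  col <- signature_collection(
    list(big = rownames(mat)[1:8], tiny = c(rownames(mat)[9], "ABSENT1",
                                            "ABSENT2", "ABSENT3")),
    c("ct1", "ct2"))
  expect_warning(res <- gsea(mat, meta, col, "A", "B", n_perm = 100, seed = 3),
                 "skipping.*tiny")
  expect_equal(res$signature, "big")
})

test_that("small groups trigger a coarse-null warning", {
  mat <- toy_matrix(20, 6, seed = 8)
  meta <- toy_metadata(mat, rep(c("A", "B"), each = 3))
  col <- signature_collection(list(s = rownames(mat)[1:6]), "ct")
  expect_warning(gsea(mat, meta, col, "A", "B", n_perm = 100, seed = 1),
                 "coarse")
})

test_that("cell-type aggregation averages NES and p over scored signatures", {
  res <- data.frame(
    signature = c("m1", "m2", "a1"),
    cell_type = c("Mono", "Mono", "aDC"),
    es = c(0.5, 0.7, -0.2), nes = c(1.0, 3.0, -0.5),
    p = c(0.02, 0.04, 0.5), padj = NA_real_,
    n_genes_used = 10L, n_perm = 100L, stringsAsFactors = FALSE)
  agg <- aggregate_by_cell_type(res)
  expect_equal(agg$mean_nes[agg$cell_type == "Mono"], 2.0)
  expect_equal(agg$mean_p[agg$cell_type == "Mono"], 0.03)
  expect_equal(agg$n_signatures, c(2L, 1L))
  # single-signature cell type: summary equals the signature
  expect_equal(agg$mean_nes[agg$cell_type == "aDC"], -0.5)
  # order invariance
  agg_rev <- aggregate_by_cell_type(res[3:1, ])
  expect_equal(agg[order(agg$cell_type), -1],
               agg_rev[order(agg_rev$cell_type), -1], ignore_attr = TRUE)
  # skipped (unscored) signatures leave the denominator
  res$nes[2] <- NA
  agg2 <- aggregate_by_cell_type(res)
  expect_equal(agg2$mean_nes[agg2$cell_type == "Mono"], 1.0)
  expect_equal(agg2$n_signatures[agg2$cell_type == "Mono"], 1L)
})
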