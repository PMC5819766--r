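test_that("gene-level metrics hit their identity and hand-computed values", {
  set.seed(2)
  m <- matrix(rnorm(200), 20, 10, dimnames = list(sprintf("g%02d", 1:20),
                                                  sprintf("c%02d", 1:10)))
  ident <- gene_level_metrics(m, m)
  expect_equal(ident$pearson, 1.0)
  expect_equal(ident$concordance, 1.0)
  expect_equal(ident$significance_overlap, 1.0)
  expect_equal(ident$mse, 0.0)

  # hand-classified concordance: statuses F,F,T,T match in both
  hand <- gene_level_metrics(c(0, 0, 2, -2), c(0.1, -0.2, 1.5, -1.8),
                             fc_threshold = 1.0)
  expect_equal(hand$concordance, 1.0)
  mixed <- gene_level_metrics(c(0, 2), c(1.5, 2), fc_threshold = 1.0)
  expect_equal(mixed$concordance, 0.5)

  # 200 entries, top 1% -> top sets of size 2; engineer exactly one shared
  a <- rep(0.1, 200); b <- rep(0.1, 200)
  a[c(7, 11)] <- c(9, 8)    # top-2 of measured
  b[c(7, 150)] <- c(9, 8)   # shares only entry 7
  overlap <- gene_level_metrics(a, b, top_fraction = 0.01)$significance_overlap
  expect_equal(overlap, 0.5)
  expect_error(gene_level_metrics(m, m[1:5, ]), "identical shapes")
})

test_that("metric invariances hold on random inputs", {
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(rnorm(120), 12, 10)
    e <- m + matrix(rnorm(120, 0, 0.5), 12, 10)
    res <- gene_level_metrics(m, e)
    expect_true(res$pearson >= -1 && res$pearson <= 1)
    expect_true(res$concordance >= 0 && res$concordance <= 1)
    expect_true(res$significance_overlap >= 0 && res$significance_overlap <= 1)
    expect_gte(res$mse, 0)
    # identical permutation of both matrices changes nothing
    perm_g <- sample(12); perm_c <- sample(10)
    res_p <- gene_level_metrics(m[perm_g, perm_c], e[perm_g, perm_c])
    expect_equal(res_p$concordance, res$concordance)
    expect_equal(res_p$mse, res$mse)
    expect_equal(res_p$pearson, res$pearson)
    # strictly monotone transform of the absolute values preserves overlap
    res_t <- gene_level_metrics(sign(m) * abs(m)^3, sign(e) * abs(e)^3)
    expect_equal(res_t$significance_overlap, res$significance_overlap)
  }
})

test_that("enrichment score walks the weighted running sum correctly", {
  fc <- stats::setNames(c(3, 2, 1, -1, -2), sprintf("g%d", 1:5))
  # top-2 set reaches the full hit mass before any miss -> ES = 1
  expect_equal(gsea_es(fc, c("g1", "g2")), 1.0)
  # bottom-concentrated set scores negative
  expect_lt(gsea_es(fc, "g5"), 0)
  expect_error(gsea_es(fc, sprintf("g%d", 1:5)), "whole universe")
  expect_error(gsea_es(fc, "absent"), "no member")

  set.seed(14)
  for (i in 1:20) {
    fcr <- stats::setNames(rnorm(30), sprintf("r%02d", 1:30))
    set_ <- sample(names(fcr), sample(1:29, 1))
    es <- gsea_es(fcr, set_)
    expect_true(es >= -1 && es <= 1)
  }
})

test_that("unweighted ES matches the brute-force KS oracle exhaustively", {
  set.seed(5)
  fc <- stats::setNames(round(rnorm(8), 3), letters[1:8])
  universe <- names(fc)
  for (size in 1:7) {
    subsets <- utils::combn(universe, size)
    for (j in seq_len(ncol(subsets))) {
      s <- subsets[, j]
      expect_equal(gsea_es(fc, s, weight_exponent = 0),
                   brute_force_ks_es(fc, s), tolerance = 1e-12)
    }
  }
})

test_that("KS pathway p-values separate shifted sets and respect the null", {
  in_ <- stats::setNames(rep(5:9, 10), sprintf("i%02d", 1:50))
  out_ <- stats::setNames(rep(-(0:4), 10), sprintf("o%02d", 1:50))
  fc <- c(in_, out_)
  expect_lt(ks_pathway_pvalue(fc, names(in_)), 1e-10)

  # same-distribution null rarely dips below the calling threshold
  set.seed(77)
  low <- 0
  for (i in 1:50) {
    fcn <- stats::setNames(rnorm(200), sprintf("n%03d", 1:200))
    p <- ks_pathway_pvalue(fcn, sample(names(fcn), 100))
    if (p <= 0.001) low <- low + 1
  }
  expect_lte(low, 1)
})

test_that("pathway score matrices have valid bounds and drop bad sets", {
  fcm <- tiny_fcm(n_genes = 15L, n_comps = 6L)
  pws <- gene_set_collection(list(P1 = rownames(fcm)[1:5],
                                  P2 = rownames(fcm)[6:9],
                                  whole = rownames(fcm),
                                  alien = c("nope1", "nope2")))
  expect_message(res <- pathway_score_matrix(fcm, pws), "dropped")
  expect_equal(rownames(res$es), c("P1", "P2"))
  expect_true(all(res$es >= -1 & res$es <= 1))
  expect_true(all(res$p > 0 & res$p <= 1))
  # duplicate comparison columns give identical ES columns
  dup <- unclass(fcm)[, c(1, 1)]
  colnames(dup) <- c("d1", "d2")
  res2 <- pathway_score_matrix(dup, pws[1:2])
  expect_equal(res2$es[, 1], res2$es[, 2], ignore_attr = TRUE)
})

test_that("differential calls apply both thresholds with signed direction", {
  es <- c(up = 0.6, weak = 0.6, down = -0.7, flat = 0.2)
  p <- c(up = 1e-5, weak = 0.01, down = 1e-4, flat = 1e-6)
  calls <- differential_pathways(es, p)
  expect_setequal(calls$pathway, c("up", "down"))
  expect_identical(calls$direction[calls$pathway == "up"], "up")
  expect_identical(calls$direction[calls$pathway == "down"], "down")
})

test_that("recall and precision follow the confusion-count definitions", {
  rp <- recall_precision(c("P1", "P2", "P3"), c("P1", "P2", "P4"))
  expect_equal(rp$recall, 2 / 3)
  expect_equal(rp$precision, 2 / 3)
  expect_equal(recall_precision(c("A"), c("A")), list(recall = 1, precision = 1))
  none <- recall_precision(c("A"), character(0))
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))
  both_empty <- recall_precision(character(0), character(0))
  expect_equal(both_empty$recall, 1)
})

test_that("cross-validation produces per-fold records plus summary", {
  spec <- synthetic_spec(n_genes = 80, n_comparisons = 48, n_studies = 8,
                         module_sizes = rep(12, 4), noise_sd = 0.1,
                         n_pathways = 10, pathway_size_range = c(4, 8),
                         seed = 19)
  corpus <- generate_foldchange_corpus(spec)
  pws <- generate_pathways(corpus$truth, spec)
  report <- suppressWarnings(cross_validate(corpus$fcm, pws,
                           selector_config = list(n = 24, q = 2, k = 3,
                                                  score_folds = 3),
                           n_folds = 2, seed = 4))
  expect_equal(sort(unique(report$folds$fold)), 1:2)
  expect_true(all(c("gene_pearson", "pathway_significance_overlap") %in%
                    report$summary$metric))
  expect_true(all(report$summary$min <= report$summary$mean + 1e-12))
  expect_true(all(report$summary$mean <= report$summary$max + 1e-12))
})

test_that("diagnostic evaluation on noiseless training data is ideal", {
  spec <- synthetic_spec(n_genes = 60, n_comparisons = 40, n_studies = 8,
                         module_sizes = rep(12, 4), noise_sd = 0,
                         n_pathways = 8, pathway_size_range = c(4, 8),
                         seed = 23)
  corpus <- generate_foldchange_corpus(spec)
  pws <- generate_pathways(corpus$truth, spec)
  panel <- sentinel_selection(unlist(lapply(corpus$truth$module_genes, head, 3)))
  rec <- evaluate_split(corpus$fcm, corpus$fcm, pws, panel = panel)
  expect_equal(rec$gene_pearson, 1.0, tolerance = 1e-8)
  expect_equal(rec$gene_mse, 0.0, tolerance = 1e-10)
  expect_equal(rec$pathway_pearson, 1.0, tolerance = 1e-6)
})
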