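test_that("tukey biweight mean matches hand-computed cases", {
  expect_equal(tukey_biweight_mean(c(5, 5, 5)), 5.0)
  expect_equal(tukey_biweight_mean(7.3), 7.3)

  # MAD = 1; the outlier sits 97/(5 * scale) > 1 scale units out, weight 0;
  # one-step value from the median is 2.602 and iteration stays nearby
  x <- c(1, 2, 3, 4, 100)
  est <- tukey_biweight_mean(x)
  expect_gt(est, 2.4)
  expect_lt(est, 2.7)
  u <- (100 - 3) / (5 * (1 + 1e-4 * 3))
  expect_gt(u, 1)  # outlier fully down-weighted

  expect_error(tukey_biweight_mean(numeric(0)), "non-empty")
  # robust against an identical-value majority (zero MAD guard)
  expect_equal(tukey_biweight_mean(c(2, 2, 2, 9)), 2)
})

test_that("eigengene count G is minimal for the variance target", {
  # component variances 81, 18, 1: cumulative fractions 0.81, 0.99
  fcm <- fcm_with_spectrum(c(81, 18, 1))
  expect_equal(compute_eigengenes(fcm, 0.9)$G, 2L)
  # three orthogonal equal-variance components: 2/3 < 0.9 <= 3/3
  expect_equal(compute_eigengenes(fcm_with_spectrum(c(4, 4, 4)), 0.9)$G, 3L)
  # rank-1 matrix
  expect_equal(compute_eigengenes(fcm_with_spectrum(5), 0.9)$G, 1L)

  decomp <- compute_eigengenes(fcm, 0.9)
  expect_equal(crossprod(decomp$loadings), diag(decomp$G), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(decomp$eigenvalues) <= 1e-8))
  expect_error(compute_eigengenes(fold_change_matrix(
    matrix(0, 3, 3, dimnames = list(letters[1:3], letters[4:6])))),
    "degenerate")
})

test_that("experiment clustering recovers well-separated clouds deterministically", {
  set.seed(11)
  cloud <- rbind(matrix(rnorm(40, 0, 0.5), 20, 2),
                 matrix(rnorm(40, 20, 0.5), 20, 2))
  # embed the 2-D clouds as comparison coordinates of a rank-2 matrix
  genes <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
  values <- genes %*% t(cloud)
  dimnames(values) <- list(sprintf("g%d", 1:6), sprintf("c%02d", 1:40))
  fcm <- fold_change_matrix(values)
  decomp <- compute_eigengenes(fcm, 0.9)
  labels <- cluster_comparisons(decomp, k = 2, seed = 1)
  expect_equal(length(unique(labels[1:20])), 1L)   # purity within cloud 1
  expect_equal(length(unique(labels[21:40])), 1L)
  expect_false(labels[1] == labels[21])
  expect_identical(labels, cluster_comparisons(decomp, k = 2, seed = 1))

  # k = number of comparisons: every comparison its own cluster
  expect_equal(sort(unname(cluster_comparisons(decomp, k = 40, seed = 1))),
               1:40)
  expect_error(cluster_comparisons(decomp, k = 41), "fewer comparisons")
})

test_that("within-cluster diversity scores conserve orthonormal mass", {
  fcm <- tiny_fcm(n_genes = 10L, n_comps = 6L)
  for (G in 1:3) {
    scores <- within_cluster_dis(fcm, G)
    expect_equal(sum(scores), G, tolerance = 1e-8)
    expect_true(all(scores >= 0))
  }
  # gene loading entirely on component 1
  values <- matrix(0, 3, 4, dimnames = list(c("a", "b", "c"), letters[4:7]))
  values["a", ] <- c(3, -1, 2, 5)
  suppressMessages(scores <- within_cluster_dis(fold_change_matrix(values), 1))
  expect_equal(unname(scores["a"]), 1.0, tolerance = 1e-10)
  expect_equal(unname(scores["b"]), 0.0)
  expect_error(within_cluster_dis(subset_comparisons(fcm, 1), 1),
               "single comparison")
})

test_that("DIS: single cluster equals within-cluster scores; planted factor dominates", {
  fcm <- tiny_fcm(n_genes = 8L, n_comps = 10L, n_studies = 5L)
  dis1 <- compute_dis(fcm, k = 1, seed = 3)
  expect_equal(dis1, within_cluster_dis(fcm, compute_eigengenes(fcm)$G),
               tolerance = 1e-10)

  # one gene carries the dominant factor in every cluster
  set.seed(5)
  z <- rnorm(30, 0, 4)
  values <- rbind(dom = 3 * z, matrix(rnorm(5 * 30, 0, 0.3), 5, 30))
  rownames(values) <- c("dom", sprintf("n%d", 1:5))
  colnames(values) <- sprintf("c%02d", 1:30)
  dis <- compute_dis(fold_change_matrix(values), k = 3, seed = 2)
  expect_equal(names(which.max(dis)), "dom")
})

test_that("study partition balances folds and never splits a study", {
  studies <- rep(sprintf("s%02d", 1:40), each = 3)
  folds <- partition_studies(studies, n_folds = 20, seed = 9)
  per_study <- tapply(folds, studies, function(v) length(unique(v)))
  expect_true(all(per_study == 1))
  counts <- table(tapply(folds, studies, unique))
  expect_true(all(counts == 2))

  # 41 studies in 20 folds: study counts in {2, 3}, exactly one fold of 3
  studies41 <- sprintf("s%02d", 1:41)
  f41 <- partition_studies(studies41, 20, seed = 9)
  counts41 <- table(f41)
  expect_setequal(as.integer(counts41), c(2L, 3L))
  expect_equal(sum(counts41 == 3), 1L)

  expect_identical(folds, partition_studies(studies, 20, seed = 9))
  expect_error(partition_studies(studies41[1:10], 20), "at least 20")
})

test_that("gene clustering groups by absolute correlation and isolates constants", {
  # proportional, anti-proportional, and constant genes
  base <- c(1, -2, 3, 0.5, -1)
  values <- rbind(a = base, b = 2 * base, c = -base, k = rep(1, 5))
  colnames(values) <- sprintf("c%d", 1:5)
  cl <- cluster_genes(fold_change_matrix(values), h = 0.9)
  expect_equal(cl[["a"]], cl[["b"]])  # r = 1 -> distance 0
  expect_equal(cl[["a"]], cl[["c"]])  # r = -1 -> |r| = 1 -> distance 0
  expect_false(cl[["k"]] %in% cl[c("a", "b", "c")])  # constant -> singleton

  # independent noise cut below its ~1 distances -> mostly singletons
  set.seed(21)
  noise <- matrix(rnorm(20 * 50), 20, 50,
                  dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:50)))
  cln <- cluster_genes(fold_change_matrix(noise), h = 0.3)
  expect_gt(mean(table(cln) == 1), 0.8)
  expect_error(cluster_genes(subset_comparisons(tiny_fcm(), 1:2)), "fewer than 3")
})

test_that("fold-wise CIS is the mean squared correlation with cluster-mates", {
  set.seed(8)
  m <- 12
  a <- rnorm(m); b <- 0.9 * a + rnorm(m, 0, 0.4); c <- -0.7 * a + rnorm(m, 0, 0.8)
  values <- rbind(a = a, b = b, c = c, lone = rnorm(m))
  colnames(values) <- sprintf("c%02d", seq_len(m))
  fcm <- fold_change_matrix(values)
  clustering <- stats::setNames(c(1L, 1L, 1L, 2L), c("a", "b", "c", "lone"))
  scores <- fold_cis(fcm, clustering)
  expect_equal(unname(scores["lone"]), 0)  # singleton scores zero
  expect_equal(unname(scores["a"]),
               mean(c(cor(a, b)^2, cor(a, c)^2)), tolerance = 1e-12)
  expect_true(all(scores >= 0 & scores <= 1))

  # two exactly proportional genes in one cluster: both score 1
  prop_values <- rbind(x = a, y = 3 * a)
  colnames(prop_values) <- sprintf("c%02d", seq_len(m))
  prop <- fold_change_matrix(prop_values)
  expect_equal(unname(fold_cis(prop, c(x = 1L, y = 1L))), c(1, 1),
               tolerance = 1e-12)
})

test_that("CIS summarises fold scores robustly and stays in [0, 1]", {
  fcm <- tiny_fcm(n_genes = 12L, n_comps = 40L, n_studies = 8L)
  cis <- compute_cis(fcm, n_folds = 4, seed = 6)
  expect_true(all(cis >= 0 & cis <= 1))
  expect_identical(cis, compute_cis(fcm, n_folds = 4, seed = 6))

  # single fold: CIS equals that fold's scores
  one <- compute_cis(fcm, n_folds = 1, seed = 6)
  sub_scores <- fold_cis(fcm, cluster_genes(fcm, 0.9))
  expect_equal(one, pmin(pmax(sub_scores, 0), 1), tolerance = 1e-12)
})

test_that("OIS follows the root-mean-square rank formula", {
  # N = 5 with prescribed ranks via distinct scores
  dis <- stats::setNames(c(1, 2, 3, 4, 5), sprintf("g%d", 1:5))
  cis <- stats::setNames(c(5, 4, 1, 3, 2), sprintf("g%d", 1:5))
  scores <- compute_ois(dis, cis)
  df <- as.data.frame(scores)
  # g4: rank_DIS = 4, rank_CIS = 3 -> sqrt((9 + 16)/2)/5
  expect_equal(df$OIS[df$gene == "g4"], sqrt(12.5) / 5, tolerance = 1e-12)
  expect_equal(df$OIS[df$gene == "g5"], sqrt((25 + 4) / 2) / 5)
  expect_true(all(sort(df$rank_DIS) == 1:5 & sort(df$rank_CIS) == 1:5))

  # boundary: top in both -> OIS = 1; bottom in both -> 1/N * sqrt(1)
  both <- compute_ois(stats::setNames(1:5, letters[1:5]),
                      stats::setNames(1:5, letters[1:5]))
  expect_equal(max(both$OIS), 1.0)
  expect_equal(min(both$OIS), sqrt(1) / 5)

  # ties resolved by gene id keep ranks a permutation
  tied <- compute_ois(stats::setNames(rep(1, 4), c("d", "b", "a", "c")),
                      stats::setNames(rep(1, 4), c("a", "b", "c", "d")))
  expect_equal(sort(tied$rank_DIS), 1:4)
  expect_identical(tied$gene[order(tied$rank_DIS)], c("a", "b", "c", "d"))

  expect_error(compute_ois(dis, cis[1:4]), "same gene universe")
})

test_that("importance scores are scale invariant and deterministic", {
  fcm <- tiny_fcm(n_genes = 10L, n_comps = 30L, n_studies = 6L)
  s1 <- compute_importance_scores(fcm, k = 3, n_folds = 3, seed = 4)
  s2 <- compute_importance_scores(fcm, k = 3, n_folds = 3, seed = 4)
  expect_identical(s1, s2)

  scaled <- fold_change_matrix(unclass(fcm) * 7, study_ids(fcm))
  s3 <- compute_importance_scores(scaled, k = 3, n_folds = 3, seed = 4)
  expect_equal(s3$CIS, s1$CIS, tolerance = 1e-9)
  expect_equal(s3$DIS, s1$DIS, tolerance = 1e-9)
})

test_that("top-n selection orders by OIS with lexicographic tie-break", {
  dis <- stats::setNames(c(3, 2, 1), c("b", "a", "c"))
  scores <- compute_ois(dis, dis)
  sel <- select_top_n(scores, 2)
  expect_identical(sel$genes, c("b", "a"))
  expect_true(all(sel$provenance == "data_driven"))
  expect_error(select_top_n(scores, 4), "exceeds")

  # tie at the cut: lexicographically smaller id wins
  tied <- compute_ois(stats::setNames(rep(1, 3), c("z", "m", "a")),
                      stats::setNames(rep(1, 3), c("z", "m", "a")))
  expect_identical(select_top_n(tied, 3)$genes, c("z", "m", "a"))
  # all OIS equal after id tie-break ranks: ranks aligned with ids
  expect_identical(select_top_n(tied, 1)$genes, "z")
})
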