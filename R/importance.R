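#' @importFrom stats cor cutree dist hclust kmeans median sd
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Eigengene decomposition of a fold-change matrix
#'
#' Computes principal components ("eigengenes") of the genes x comparisons
#' matrix by singular value decomposition and retains the smallest number G
#' of components whose cumulative variance fraction reaches `var_fraction`.
#' Fold changes are differential contrasts already, so no centering is
#' applied by default; "variance" of a component is its squared singular
#' value.
#'
#' @param fcm a [fold_change_matrix()] with at least 2 genes and 2
#'   comparisons.
#' @param var_fraction target cumulative explained-variance fraction in
#'   (0, 1]; default 0.9.
#' @param center `"none"` (default) or `"gene-mean"` to subtract each gene's
#'   mean fold change first.
#' @return an object of class `eigengene_decomposition`: list with `G`,
#'   `loadings` (genes x G, orthonormal columns), `scores` (comparisons x G
#'   component coordinates), `eigenvalues` (all squared singular values,
#'   non-increasing) and `total_variance`.
#' @export
compute_eigengenes <- function(fcm, var_fraction = 0.9, center = c("none", "gene-mean")) {
  center <- match.arg(center)
  if (nrow(fcm) < 2L || ncol(fcm) < 2L)
    stop("need at least 2 genes and 2 comparisons")
  if (var_fraction <= 0 || var_fraction > 1)
    stop("`var_fraction` must be in (0, 1]")
  x <- unclass(fcm)
  if (center == "gene-mean") x <- x - rowMeans(x)
  sv <- svd(x)
  ev <- sv$d^2
  total <- sum(ev)
  if (total == 0) stop("degenerate input: fold-change matrix has zero variance")
  G <- which(cumsum(ev) / total >= var_fraction - 1e-12)[1L]
  loadings <- sv$u[, seq_len(G), drop = FALSE]
  rownames(loadings) <- rownames(fcm)
  scores <- sv$v[, seq_len(G), drop = FALSE] %*% diag(sv$d[seq_len(G)], G)
  rownames(scores) <- colnames(fcm)
  structure(list(G = G, loadings = loadings, scores = scores,
                 eigenvalues = ev, total_variance = total, center = center),
            class = "eigengene_decomposition")
}

# k-means++ seeding: spread initial centers with probability proportional to
# squared distance from the centers already chosen.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      pool <- setdiff(seq_len(n), centers[seq_len(j - 1L)])
      centers[j] <- if (length(pool)) sample(pool, 1L) else sample.int(n, 1L)
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums((x - matrix(x[centers[j], ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' Cluster comparisons (experiments) on their eigengene coordinates
#'
#' k-means with Euclidean distance on the comparisons' component coordinates,
#' k-means++ seeding, `n_restarts` restarts keeping the lowest total
#' within-cluster sum of squares. Deterministic given `seed`.
#'
#' @param decomp an `eigengene_decomposition`.
#' @param k number of clusters (default 10).
#' @param seed RNG seed.
#' @param n_restarts independent k-means++ restarts (default 10).
#' @return integer cluster label per comparison, named by comparison id.
#' @export
cluster_comparisons <- function(decomp, k = 10L, seed = 1L, n_restarts = 10L) {
  x <- decomp$scores
  if (nrow(x) < k) stop("fewer comparisons (", nrow(x), ") than clusters k = ", k)
  if (k == nrow(x)) {
    labels <- seq_len(nrow(x))
    names(labels) <- rownames(x)
    return(labels)
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- x[kmeanspp_centers(x, k), , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(kmeans(x, centers = init, iter.max = 100L)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss))
        best <- fit
    }
    if (is.null(best)) stop("k-means failed on all restarts (k = ", k, ")")
    labels <- best$cluster
    names(labels) <- rownames(x)
    labels
  })
}

# Numerical rank of a singular value spectrum.
spectrum_rank <- function(d, tol = NULL) {
  if (!length(d) || d[1L] == 0) return(0L)
  if (is.null(tol)) tol <- max(d) * 1e-10
  sum(d > tol)
}

#' Within-cluster diversity scores
#'
#' Recomputes principal components on one experiment cluster's comparisons
#' and scores each gene by the sum of its squared loadings on the first G
#' components. Because loading columns are orthonormal, the scores of all
#' genes sum to `min(G, rank of the cluster submatrix)`.
#'
#' @param fcm_subset a [fold_change_matrix()] restricted to one cluster's
#'   comparisons (at least 2).
#' @param G number of leading components to sum over; truncated (with a
#'   message) when the cluster has fewer non-degenerate components.
#' @param center as in [compute_eigengenes()].
#' @return named non-negative numeric vector, one score per gene.
#' @export
within_cluster_dis <- function(fcm_subset, G, center = c("none", "gene-mean")) {
  center <- match.arg(center)
  if (ncol(fcm_subset) < 2L)
    stop("cluster has a single comparison; no within-cluster components")
  if (G < 1L) stop("`G` must be >= 1")
  x <- unclass(fcm_subset)
  if (center == "gene-mean") x <- x - rowMeans(x)
  sv <- svd(x)
  avail <- spectrum_rank(sv$d)
  if (avail == 0L) {
    out <- numeric(nrow(x)); names(out) <- rownames(x)
    return(out)
  }
  Gc <- min(G, avail)
  if (Gc < G)
    message("cluster supports only ", Gc, " of ", G, " requested components")
  out <- rowSums(sv$u[, seq_len(Gc), drop = FALSE]^2)
  names(out) <- rownames(x)
  out
}

#' Diversity importance score (DIS)
#'
#' Scores every gene for how strongly it participates in the dominant
#' expression programs across diverse experimental conditions: experiments
#' are clustered on their global eigengene coordinates, each cluster
#' contributes per-gene summed squared loadings on its leading components,
#' and the per-cluster scores are summarised by the robust Tukey biweight
#' mean.
#'
#' @param fcm a [fold_change_matrix()].
#' @param k number of experiment clusters (default 10).
#' @param var_fraction explained-variance target fixing G (default 0.9).
#' @param seed RNG seed for the experiment clustering.
#' @param biweight_c Tukey biweight tuning constant.
#' @param center PCA centering convention.
#' @return named numeric vector of non-negative DIS values, one per gene.
#' @export
compute_dis <- function(fcm, k = 10L, var_fraction = 0.9, seed = 1L,
                        biweight_c = 5, center = c("none", "gene-mean")) {
  center <- match.arg(center)
  decomp <- compute_eigengenes(fcm, var_fraction, center)
  labels <- cluster_comparisons(decomp, k = k, seed = seed)
  per_cluster <- list()
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) {
      warning("cluster ", cl, " has a single comparison; skipped in DIS")
      next
    }
    per_cluster[[length(per_cluster) + 1L]] <-
      within_cluster_dis(subset_comparisons(fcm, idx), decomp$G, center)
  }
  if (!length(per_cluster))
    stop("no experiment cluster had >= 2 comparisons; cannot compute DIS")
  mat <- do.call(cbind, per_cluster)
  apply(mat, 1L, tukey_biweight_mean, c = biweight_c)
}

#' Partition studies into folds
#'
#' Randomly assigns whole studies to `n_folds` folds of near-equal study
#' count (sizes differ by at most one), so that comparisons from one study
#' never straddle folds.
#'
#' @param study_ids character vector of study labels, one per comparison.
#' @param n_folds number of folds (default 20).
#' @param seed RNG seed.
#' @return integer fold label in `1..n_folds` per comparison.
#' @export
partition_studies <- function(study_ids, n_folds = 20L, seed = 1L) {
  studies <- unique(study_ids)
  if (length(studies) < n_folds)
    stop("need at least ", n_folds, " distinct studies, have ", length(studies))
  with_seed(seed, {
    shuffled <- sample(studies)
    fold_of_study <- stats::setNames(rep_len(seq_len(n_folds), length(studies)),
                                     shuffled)
    as.integer(fold_of_study[study_ids])
  })
}

#' Cluster genes within one fold by absolute-correlation distance
#'
#' Hierarchical clustering (average linkage) of genes under the distance
#' `1 - |Pearson r|` across the fold's comparisons, cut at height `h`. The
#' absolute value groups anti-correlated partners together: either one
#' predicts the other. Genes with zero variance within the fold have no
#' defined correlation and are isolated as singletons.
#'
#' @param fcm_subset a [fold_change_matrix()] restricted to one fold's
#'   comparisons (at least 3 for a non-degenerate correlation).
#' @param h cut height on the 1-|r| scale (default 0.9).
#' @return integer cluster label per gene, named by gene id.
#' @export
cluster_genes <- function(fcm_subset, h = 0.9) {
  if (ncol(fcm_subset) < 3L)
    stop("fold has fewer than 3 comparisons; correlations would be degenerate")
  x <- unclass(fcm_subset)
  sds <- apply(x, 1L, sd)
  ok <- sds > 0
  labels <- integer(nrow(x))
  names(labels) <- rownames(x)
  n_ok <- sum(ok)
  if (n_ok >= 2L) {
    cr <- cor(t(x[ok, , drop = FALSE]))
    d <- 1 - abs(cr)
    d[d < 0] <- 0  # guard rounding below zero
    hc <- hclust(stats::as.dist(d), method = "average")
    labels[ok] <- cutree(hc, h = h)
  } else if (n_ok == 1L) {
    labels[ok] <- 1L
  }
  # constant genes become their own singleton clusters
  n_used <- max(labels, 0L)
  labels[!ok] <- n_used + seq_len(sum(!ok))
  labels
}

#' Fold-wise co-expression scores
#'
#' Within one fold, a gene's score is the average squared Pearson
#' correlation between its fold-change profile and each other gene in the
#' same cluster; genes in singleton clusters score 0.
#'
#' @param fcm_subset the fold's [fold_change_matrix()].
#' @param clustering gene cluster labels from [cluster_genes()].
#' @return named numeric vector in `[0, 1]`, one score per gene.
#' @export
fold_cis <- function(fcm_subset, clustering) {
  if (!setequal(names(clustering), rownames(fcm_subset)) ||
      length(clustering) != nrow(fcm_subset))
    stop("`clustering` must assign every gene of the subset exactly once")
  x <- unclass(fcm_subset)
  out <- numeric(nrow(x))
  names(out) <- rownames(x)
  for (cl in unique(clustering)) {
    members <- names(clustering)[clustering == cl]
    if (length(members) < 2L) next
    cr <- cor(t(x[members, , drop = FALSE]))
    out[members] <- (rowSums(cr^2) - 1) / (length(members) - 1L)
  }
  pmin(pmax(out, 0), 1)
}

#' Co-expression importance score (CIS)
#'
#' Studies are partitioned into `n_folds` folds; within each usable fold
#' genes are clustered under the 1-|r| distance and scored by their average
#' squared correlation with cluster-mates; the fold-wise scores are
#' summarised by the Tukey biweight mean.
#'
#' @param fcm a [fold_change_matrix()].
#' @param n_folds number of study folds (default 20).
#' @param h hierarchical-clustering cut height (default 0.9).
#' @param seed RNG seed for the study partition.
#' @param biweight_c Tukey biweight tuning constant.
#' @return named numeric vector in `[0, 1]`, one CIS per gene.
#' @export
compute_cis <- function(fcm, n_folds = 20L, h = 0.9, seed = 1L, biweight_c = 5) {
  folds <- partition_studies(study_ids(fcm), n_folds, seed)
  per_fold <- list()
  for (f in seq_len(n_folds)) {
    idx <- which(folds == f)
    if (length(idx) < 3L) {
      warning("fold ", f, " has fewer than 3 comparisons; skipped in CIS")
      next
    }
    sub <- subset_comparisons(fcm, idx)
    per_fold[[length(per_fold) + 1L]] <- fold_cis(sub, cluster_genes(sub, h))
  }
  if (!length(per_fold))
    stop("no fold had >= 3 comparisons; cannot compute CIS")
  mat <- do.call(cbind, per_fold)
  pmin(pmax(apply(mat, 1L, tukey_biweight_mean, c = biweight_c), 0), 1)
}

# Ranks 1..N ascending in score, ties resolved by ascending gene id so the
# ranks stay a permutation.
rank_with_id_ties <- function(score, gene) {
  ord <- order(score, gene)
  r <- integer(length(score))
  r[ord] <- seq_along(score)
  r
}

#' Overall importance score (OIS)
#'
#' Combines DIS and CIS into one selection criterion: both scores are ranked
#' from smallest to largest (rank N = best) and the OIS is the
#' root-mean-square of the two ranks scaled by the gene count,
#' `OIS(g) = sqrt((rank_CIS(g)^2 + rank_DIS(g)^2) / 2) / N`, so values lie in
#' (0, 1] with 1 attained only by a gene ranked top in both.
#'
#' @param dis named numeric vector of DIS values.
#' @param cis named numeric vector of CIS values over the same genes.
#' @return an object of class `importance_scores`: list with `gene`, `DIS`,
#'   `CIS`, `rank_DIS`, `rank_CIS`, `OIS`, `N`.
#' @export
compute_ois <- function(dis, cis) {
  if (is.null(names(dis)) || is.null(names(cis)))
    stop("`dis` and `cis` must be named by gene")
  if (!setequal(names(dis), names(cis)) || length(dis) != length(cis))
    stop("`dis` and `cis` must cover the same gene universe")
  genes <- sort(names(dis))
  dis <- dis[genes]; cis <- cis[genes]
  N <- length(genes)
  rank_dis <- rank_with_id_ties(dis, genes)
  rank_cis <- rank_with_id_ties(cis, genes)
  ois <- sqrt((rank_cis^2 + rank_dis^2) / 2) / N
  structure(list(gene = genes, DIS = unname(dis), CIS = unname(cis),
                 rank_DIS = rank_dis, rank_CIS = rank_cis,
                 OIS = ois, N = N),
            class = "importance_scores")
}

#' @export
as.data.frame.importance_scores <- function(x, ...) {
  data.frame(gene = x$gene, DIS = x$DIS, CIS = x$CIS,
             rank_DIS = x$rank_DIS, rank_CIS = x$rank_CIS, OIS = x$OIS,
             stringsAsFactors = FALSE)
}

#' @export
print.importance_scores <- function(x, ...) {
  cat(sprintf("importance_scores for %d genes (OIS in [%.3f, %.3f])\n",
              x$N, min(x$OIS), max(x$OIS)))
  invisible(x)
}

#' Compute all importance scores in one call
#'
#' Convenience wrapper running DIS, CIS and OIS with independent seed
#' substreams derived from `seed`.
#'
#' @inheritParams compute_dis
#' @inheritParams compute_cis
#' @return an `importance_scores` object.
#' @export
compute_importance_scores <- function(fcm, k = 10L, var_fraction = 0.9,
                                      n_folds = 20L, h = 0.9, biweight_c = 5,
                                      seed = 1L, center = c("none", "gene-mean")) {
  center <- match.arg(center)
  dis <- compute_dis(fcm, k = k, var_fraction = var_fraction,
                     seed = seed * 2L + 1L, biweight_c = biweight_c,
                     center = center)
  cis <- compute_cis(fcm, n_folds = n_folds, h = h,
                     seed = seed * 2L + 2L, biweight_c = biweight_c)
  compute_ois(dis, cis)
}

#' Select the top-n genes by OIS
#'
#' @param scores an `importance_scores` object.
#' @param n panel size (default 1500); ties at the cut are resolved by
#'   ascending gene identifier.
#' @return a `sentinel_selection`: list with `genes` (ordered by descending
#'   OIS), `provenance` (all `"data_driven"`) and `parameters`.
#' @export
select_top_n <- function(scores, n = 1500L) {
  if (n > scores$N)
    stop("requested n = ", n, " exceeds the ", scores$N, "-gene universe")
  if (n < 1L) stop("`n` must be >= 1")
  ord <- order(-scores$OIS, scores$gene)
  genes <- scores$gene[ord][seq_len(n)]
  sentinel_selection(genes, rep("data_driven", n),
                     parameters = list(n = n))
}

#' Construct a sentinel selection
#'
#' @param genes ordered character vector of unique gene identifiers.
#' @param provenance character vector: `"data_driven"`,
#'   `"coverage_replacement"` or `"nominated"` per gene.
#' @param parameters list of the parameters that produced the selection.
#' @return an object of class `sentinel_selection`.
#' @export
sentinel_selection <- function(genes,
                               provenance = rep("data_driven", length(genes)),
                               parameters = list()) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("selection contains duplicate genes")
  provenance <- as.character(provenance)
  if (length(provenance) != length(genes))
    stop("`provenance` must match `genes` in length")
  bad <- setdiff(provenance, c("data_driven", "coverage_replacement", "nominated"))
  if (length(bad)) stop("unknown provenance value(s): ", paste(bad, collapse = ", "))
  structure(list(genes = genes, provenance = stats::setNames(provenance, genes),
                 parameters = parameters),
            class = "sentinel_selection")
}

#' @export
print.sentinel_selection <- function(x, ...) {
  tab <- table(x$provenance)
  cat(sprintf("sentinel_selection: %d genes (%s)\n", length(x$genes),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
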