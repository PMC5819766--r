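#' Gene-level agreement metrics between measured and extrapolated values
#'
#' Four pooled metrics over all (gene, comparison) entries:
#' \itemize{
#'   \item \strong{pearson} — Pearson correlation of the pooled entries;
#'   \item \strong{concordance} — fraction of entries whose binary
#'     changed/unchanged status (absolute value at least `fc_threshold`)
#'     agrees, i.e. (TP + TN) / (TP + TN + FP + FN);
#'   \item \strong{significance_overlap} — fraction of the top
#'     `top_fraction` entries by absolute value (ceiling size, ties broken
#'     by entry index for determinism) shared between the two matrices;
#'   \item \strong{mse} — mean squared entrywise difference.
#' }
#'
#' @param measured,extrapolated numeric matrices of identical shape (or
#'   equal-length vectors).
#' @param fc_threshold changed/unchanged cutoff on the absolute value
#'   (default 1.0, i.e. two-fold on the log2 scale).
#' @param top_fraction fraction of entries forming the "significant" top
#'   sets (default 0.01).
#' @return list with `pearson`, `concordance`, `significance_overlap`,
#'   `mse`.
#' @export
gene_level_metrics <- function(measured, extrapolated, fc_threshold = 1.0,
                               top_fraction = 0.01) {
  m <- as.vector(measured); e <- as.vector(extrapolated)
  if (length(m) != length(e))
    stop("`measured` and `extrapolated` must have identical shapes")
  if (length(m) < 2L) stop("need at least 2 entries")
  pearson <- if (stats::sd(m) == 0 || stats::sd(e) == 0) NA_real_
             else stats::cor(m, e)
  concordance <- mean((abs(m) >= fc_threshold) == (abs(e) >= fc_threshold))
  n_top <- max(1L, ceiling(top_fraction * length(m)))
  top_m <- order(-abs(m), seq_along(m))[seq_len(n_top)]
  top_e <- order(-abs(e), seq_along(e))[seq_len(n_top)]
  list(pearson = pearson,
       concordance = concordance,
       significance_overlap = length(intersect(top_m, top_e)) / n_top,
       mse = mean((m - e)^2))
}

#' Fold-change-ranked enrichment score (GSEA running sum)
#'
#' Genes are ranked by fold change from largest to smallest (ties broken by
#' gene identifier) and a weighted Kolmogorov-Smirnov running sum is walked
#' down the list: hits increment by `|fc|^p` normalised by the total hit
#' mass, misses decrement by 1/(N - Nh). The enrichment score is the
#' running-sum value of maximum absolute deviation, in [-1, 1]; positive
#' scores mean the set concentrates among up-regulated genes. With
#' `weight_exponent = 0` this reduces to the classic unweighted KS
#' statistic.
#'
#' @param fold_changes named numeric vector, one fold change per gene in the
#'   ranked universe.
#' @param gene_set character vector of member gene ids.
#' @param weight_exponent exponent p on `|fc|` for hit weights (default 1).
#' @return a single enrichment score in [-1, 1].
#' @export
gsea_es <- function(fold_changes, gene_set, weight_exponent = 1) {
  if (is.null(names(fold_changes))) stop("`fold_changes` must be named by gene")
  genes <- names(fold_changes)
  hit <- genes %in% gene_set
  n_hit <- sum(hit); n <- length(genes)
  if (n_hit == 0L) stop("gene set has no member in the ranked universe")
  if (n_hit == n) stop("gene set covers the whole universe; ES undefined")
  ord <- order(-fold_changes, genes)
  hit <- hit[ord]
  w <- abs(fold_changes[ord])^weight_exponent
  hit_mass <- sum(w[hit])
  inc <- if (hit_mass > 0) w * hit / hit_mass else hit / n_hit
  dec <- (!hit) / (n - n_hit)
  running <- cumsum(inc - dec)
  es <- running[which.max(abs(running))]
  max(-1, min(1, es))
}

#' Two-sample KS significance of a pathway's fold changes
#'
#' Asymptotic two-sample Kolmogorov-Smirnov p-value comparing the in-set
#' fold-change distribution against the out-of-set distribution.
#'
#' @inheritParams gsea_es
#' @return p-value in (0, 1].
#' @export
ks_pathway_pvalue <- function(fold_changes, gene_set) {
  if (is.null(names(fold_changes))) stop("`fold_changes` must be named by gene")
  inside <- names(fold_changes) %in% gene_set
  if (!any(inside)) stop("gene set has no member in the ranked universe")
  if (all(inside)) stop("gene set covers the whole universe; test undefined")
  suppressWarnings(
    stats::ks.test(fold_changes[inside], fold_changes[!inside],
                   exact = FALSE)$p.value)
}

#' Pathway enrichment score matrix across comparisons
#'
#' Applies [gsea_es()] and [ks_pathway_pvalue()] column-wise. Pathways with
#' no gene in the matrix's universe (or covering all of it) are dropped
#' with a message.
#'
#' @param fcm a [fold_change_matrix()] or plain named numeric matrix.
#' @param pathways a `gene_set_collection`.
#' @param weight_exponent passed to [gsea_es()].
#' @return list with `es` and `p` (pathways x comparisons matrices) and
#'   `set_size` (genes of each retained pathway present in the universe).
#' @export
pathway_score_matrix <- function(fcm, pathways, weight_exponent = 1) {
  x <- unclass(fcm)
  universe <- rownames(x)
  n_in <- vapply(pathways, function(s) sum(s %in% universe), 0L)
  keep <- n_in > 0L & n_in < length(universe)
  if (!all(keep))
    message(sum(!keep), " pathway(s) dropped (empty or universe-covering)")
  pws <- pathways[keep]
  es <- matrix(NA_real_, length(pws), ncol(x),
               dimnames = list(names(pws), colnames(x)))
  p <- es
  for (j in seq_len(ncol(x))) {
    fc <- stats::setNames(x[, j], universe)
    for (i in seq_along(pws)) {
      es[i, j] <- gsea_es(fc, pws[[i]], weight_exponent)
      p[i, j] <- ks_pathway_pvalue(fc, pws[[i]])
    }
  }
  list(es = es, p = p, set_size = n_in[keep])
}

#' Call differentially regulated pathways
#'
#' A pathway is called differential when its absolute enrichment score
#' exceeds `es_threshold` and its KS p-value falls below `p_threshold`;
#' the direction is the sign of the enrichment score.
#'
#' @param es named numeric vector of enrichment scores (one comparison).
#' @param p named numeric vector of KS p-values over the same pathways.
#' @param es_threshold absolute-ES cutoff (default 0.5).
#' @param p_threshold p-value cutoff (default 0.001).
#' @return data frame with columns `pathway` and `direction` ("up"/"down").
#' @export
differential_pathways <- function(es, p, es_threshold = 0.5, p_threshold = 0.001) {
  if (!identical(names(es), names(p)))
    stop("`es` and `p` must be aligned over the same pathways")
  hit <- abs(es) > es_threshold & p < p_threshold
  data.frame(pathway = names(es)[hit],
             direction = ifelse(es[hit] > 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Recall and precision of a differential-pathway call set
#'
#' @param truth character vector (or data frame with `pathway` column) of
#'   truly differential pathways.
#' @param predicted character vector (or data frame) of called pathways.
#' @return list with `recall` (1 when both sets are empty, NA when truth is
#'   empty but predictions exist) and `precision` (NA when nothing was
#'   predicted but truth is non-empty).
#' @export
recall_precision <- function(truth, predicted) {
  as_set <- function(x) if (is.data.frame(x)) unique(x$pathway) else unique(as.character(x))
  truth <- as_set(truth); predicted <- as_set(predicted)
  tp <- length(intersect(truth, predicted))
  recall <- if (length(truth)) tp / length(truth)
            else if (!length(predicted)) 1.0 else NA_real_
  precision <- if (length(predicted)) tp / length(predicted)
               else if (!length(truth)) 1.0 else NA_real_
  list(recall = recall, precision = precision)
}

# Default per-run configuration for panel selection inside cross-validation.
default_selector_config <- function() {
  list(method = "ois", n = 1500L, q = 3L, k = 10L, var_fraction = 0.9,
       score_folds = 20L, h = 0.9, biweight_c = 5,
       lambda = 0.01, fc_threshold = 1.0, top_fraction = 0.01,
       es_threshold = 0.5, p_threshold = 0.001, weight_exponent = 1)
}

# Select a panel on a training matrix according to a selector config.
select_panel <- function(train, pathways, config, seed) {
  if (config$method == "random") {
    genes <- with_seed(seed, sample(rownames(train), config$n))
    return(sentinel_selection(genes, parameters = list(n = config$n,
                                                       method = "random")))
  }
  scores <- compute_importance_scores(
    train, k = config$k, var_fraction = config$var_fraction,
    n_folds = config$score_folds, h = config$h,
    biweight_c = config$biweight_c, seed = seed)
  initial <- select_top_n(scores, config$n)
  refine_selection(initial, pathways, q = config$q, scores = scores,
                   universe = rownames(train))
}

#' Cross-validated panel evaluation
#'
#' Studies are partitioned into `n_folds` folds. For each fold the panel is
#' selected on the retained folds (full importance scoring plus pathway
#' refinement, or a size-matched random draw when
#' `selector_config$method = "random"`), the extrapolation model is fitted
#' on the retained folds, and the held-out fold is reconstructed from its
#' sentinel rows. Gene-level metrics compare measured vs extrapolated
#' values of the non-sentinel genes; pathway-level metrics compare
#' enrichment scores computed from the full measured profile vs the
#' sentinel-plus-extrapolated profile (pooled over pathways and held-out
#' comparisons, with the concordance/top-set cutoffs applied on the ES
#' scale).
#'
#' @param fcm a [fold_change_matrix()].
#' @param pathways a `gene_set_collection`.
#' @param selector_config list overriding entries of the default selector
#'   configuration (`method`, `n`, `q`, `k`, `var_fraction`, `score_folds`,
#'   `h`, `biweight_c`, `lambda`, thresholds).
#' @param n_folds number of cross-validation folds (default 20).
#' @param seed RNG seed; folds and per-fold selection use derived
#'   substreams.
#' @return an `evaluation_report`: list with `folds` (per-fold data frame of
#'   gene- and pathway-level metrics) and `summary` (mean, min, max per
#'   metric).
#' @export
cross_validate <- function(fcm, pathways, selector_config = list(),
                           n_folds = 20L, seed = 1L) {
  config <- utils::modifyList(default_selector_config(), selector_config)
  folds <- partition_studies(study_ids(fcm), n_folds, seed)
  records <- list()
  for (f in seq_len(n_folds)) {
    test_idx <- which(folds == f)
    train <- subset_comparisons(fcm, which(folds != f))
    test <- subset_comparisons(fcm, test_idx)
    rec <- tryCatch(
      evaluate_split(train, test, pathways, config, seed = seed * 100L + f),
      error = function(e) {
        warning("fold ", f, " skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(rec)) records[[length(records) + 1L]] <- cbind(fold = f, rec)
  }
  if (!length(records)) stop("every cross-validation fold was degenerate")
  folds_df <- do.call(rbind, records)
  metrics <- setdiff(names(folds_df), "fold")
  summary_df <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds_df[[m]], na.rm = TRUE), 0),
    min = vapply(metrics, function(m) min(folds_df[[m]], na.rm = TRUE), 0),
    max = vapply(metrics, function(m) max(folds_df[[m]], na.rm = TRUE), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(folds = folds_df, summary = summary_df, config = config),
            class = "evaluation_report")
}

#' Evaluate a panel on an explicit train/test split
#'
#' Selects (or reuses) a panel on the training matrix, fits extrapolation
#' on it, reconstructs the test matrix from its sentinel rows, and returns
#' one row of gene-level and pathway-level metrics.
#'
#' @param train,test [fold_change_matrix()] objects over the same genes.
#' @param pathways a `gene_set_collection`.
#' @param config selector configuration (see [cross_validate()]).
#' @param seed RNG seed for selection.
#' @param panel optional pre-computed `sentinel_selection`; skips selection.
#' @return one-row data frame of metrics (`gene_*` and `pathway_*`).
#' @export
evaluate_split <- function(train, test, pathways, config = list(), seed = 1L,
                           panel = NULL) {
  config <- utils::modifyList(default_selector_config(), config)
  if (is.null(panel)) panel <- select_panel(train, pathways, config, seed)
  model <- fit_extrapolation(train, panel$genes, lambda = config$lambda)
  measured_targets <- unclass(test)[model$target_genes, , drop = FALSE]
  predicted <- extrapolate(model, unclass(test)[model$sentinel_genes, , drop = FALSE])
  g <- gene_level_metrics(measured_targets, predicted,
                          fc_threshold = config$fc_threshold,
                          top_fraction = config$top_fraction)
  full_measured <- unclass(test)[c(model$sentinel_genes, model$target_genes), ,
                                 drop = FALSE]
  full_pred <- full_profile(model, unclass(test)[model$sentinel_genes, ,
                                                 drop = FALSE])
  es_m <- pathway_score_matrix(full_measured, pathways,
                               config$weight_exponent)$es
  es_e <- pathway_score_matrix(full_pred, pathways, config$weight_exponent)$es
  common <- intersect(rownames(es_m), rownames(es_e))
  pw <- gene_level_metrics(es_m[common, , drop = FALSE],
                           es_e[common, , drop = FALSE],
                           fc_threshold = config$es_threshold,
                           top_fraction = config$top_fraction)
  data.frame(gene_pearson = g$pearson, gene_concordance = g$concordance,
             gene_significance_overlap = g$significance_overlap, gene_mse = g$mse,
             pathway_pearson = pw$pearson, pathway_concordance = pw$concordance,
             pathway_significance_overlap = pw$significance_overlap,
             pathway_mse = pw$mse, stringsAsFactors = FALSE)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report over", nrow(x$folds), "fold(s)\n")
  print(x$summary, digits = 3)
  invisible(x)
}
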