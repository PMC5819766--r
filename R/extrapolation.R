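#' Fit a principal-component-regression extrapolation model
#'
#' Builds the linear operator that predicts non-sentinel fold changes from
#' sentinel fold changes. The sentinel submatrix is decomposed into
#' eigengenes (uncentered SVD by default); the first K components are kept,
#' K being the largest index whose component variance is at least `lambda`
#' times the leading one. Each non-sentinel gene is regressed on the K
#' component coordinates (orthogonal regressors, so ordinary least squares
#' is exact and needs no regularisation — rank deficiency is handled by the
#' lambda cutoff), and the extrapolation matrix is the product of the
#' regression coefficient matrix with the transposed loading matrix.
#'
#' @param fcm training [fold_change_matrix()] holding sentinels and targets.
#' @param sentinels ordered character vector of sentinel gene ids, all
#'   present in `fcm`.
#' @param lambda eigenvalue-ratio threshold in (0, 1] (default 0.01).
#' @param center `"none"` (default; the model is then linear-homogeneous) or
#'   `"gene-mean"` (gene means are removed for fitting and added back on
#'   application).
#' @return an object of class `extrapolation_model`: list with
#'   `sentinel_genes`, `target_genes`, `K`, `loadings` (s x K),
#'   `coefficients` (t x K), `extrapolation_matrix` (t x s), `lambda`,
#'   `eigenvalues`, and centering offsets.
#' @export
fit_extrapolation <- function(fcm, sentinels, lambda = 0.01,
                              center = c("none", "gene-mean")) {
  center <- match.arg(center)
  sentinels <- as.character(sentinels)
  missing <- setdiff(sentinels, rownames(fcm))
  if (length(missing))
    stop("sentinel gene(s) absent from training matrix: ",
         paste(missing, collapse = ", "))
  if (lambda <= 0 || lambda > 1) stop("`lambda` must be in (0, 1]")
  targets <- setdiff(rownames(fcm), sentinels)
  if (!length(targets)) stop("no non-sentinel genes to extrapolate")
  if (ncol(fcm) < 2L) stop("need at least 2 training comparisons")
  xs <- unclass(fcm)[sentinels, , drop = FALSE]
  xt <- unclass(fcm)[targets, , drop = FALSE]
  mu_s <- if (center == "gene-mean") rowMeans(xs) else numeric(length(sentinels))
  mu_t <- if (center == "gene-mean") rowMeans(xt) else numeric(length(targets))
  xs_c <- xs - mu_s
  xt_c <- xt - mu_t
  sv <- svd(xs_c)
  ev <- sv$d^2
  if (ev[1L] == 0) stop("degenerate input: sentinel matrix has zero variance")
  K <- max(which(ev / ev[1L] >= lambda))
  loadings <- sv$u[, seq_len(K), drop = FALSE]          # s x K
  rownames(loadings) <- sentinels
  # component coordinates per comparison: t(loadings) %*% xs_c = d * t(v)
  # OLS on orthogonal scores: B = xt_c %*% v[,1:K] %*% diag(1/d[1:K])
  coef <- xt_c %*% sv$v[, seq_len(K), drop = FALSE] %*%
    diag(1 / sv$d[seq_len(K)], K)                        # t x K
  rownames(coef) <- targets
  amat <- coef %*% t(loadings)                           # t x s
  dimnames(amat) <- list(targets, sentinels)
  structure(list(sentinel_genes = sentinels, target_genes = targets,
                 K = K, loadings = loadings, coefficients = coef,
                 extrapolation_matrix = amat, lambda = lambda,
                 eigenvalues = ev, center = center,
                 sentinel_means = mu_s, target_means = mu_t),
            class = "extrapolation_model")
}

#' @export
print.extrapolation_model <- function(x, ...) {
  cat(sprintf("extrapolation_model: %d sentinels -> %d targets, K = %d (lambda = %g)\n",
              length(x$sentinel_genes), length(x$target_genes), x$K, x$lambda))
  invisible(x)
}

# Validate and order a sentinel fold-change input against the model.
align_sentinel_input <- function(model, sentinel_fc) {
  if (is.vector(sentinel_fc)) sentinel_fc <- matrix(sentinel_fc, ncol = 1L,
    dimnames = list(names(sentinel_fc), "fc"))
  s <- length(model$sentinel_genes)
  if (!is.null(rownames(sentinel_fc))) {
    missing <- setdiff(model$sentinel_genes, rownames(sentinel_fc))
    if (length(missing))
      stop("sentinel rows missing from input: ", paste(missing, collapse = ", "))
    sentinel_fc <- sentinel_fc[model$sentinel_genes, , drop = FALSE]
  } else if (nrow(sentinel_fc) != s) {
    stop("input has ", nrow(sentinel_fc), " rows but the model expects ", s,
         " sentinel genes")
  }
  sentinel_fc
}

#' Extrapolate non-sentinel fold changes from sentinel measurements
#'
#' Applies the model's extrapolation matrix: a linear map from the s
#' sentinel fold changes of each comparison to the t target-gene fold
#' changes (plus the gene-mean offsets for a centered model).
#'
#' @param model an `extrapolation_model`.
#' @param sentinel_fc numeric matrix s x m (or a length-s vector), rows
#'   ordered as (or named by) `model$sentinel_genes`.
#' @return numeric matrix t x m of predicted fold changes, rows named by
#'   target gene.
#' @export
extrapolate <- function(model, sentinel_fc) {
  x <- align_sentinel_input(model, sentinel_fc)
  out <- model$extrapolation_matrix %*% (x - model$sentinel_means) +
    model$target_means
  rownames(out) <- model$target_genes
  colnames(out) <- colnames(x)
  out
}

#' Assemble a full transcriptome profile from sentinel measurements
#'
#' Sentinel rows pass through unchanged; target rows are extrapolated. Rows
#' are ordered sentinels first, then targets.
#'
#' @inheritParams extrapolate
#' @return numeric (s + t) x m matrix.
#' @export
full_profile <- function(model, sentinel_fc) {
  x <- align_sentinel_input(model, sentinel_fc)
  rownames(x) <- model$sentinel_genes
  rbind(x, extrapolate(model, x))
}
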