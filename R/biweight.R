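#' Tukey biweight mean
#'
#' Robust location estimate used to summarise per-cluster diversity scores
#' and per-fold co-expression scores across clusters/folds. Starting from the
#' median, observations are iteratively reweighted with Tukey's bisquare
#' weight `(1 - u^2)^2` for `|u| < 1` (0 otherwise), where
#' `u = (x - t) / (c * s)` and the scale `s = MAD + eps * median(|x|)` is the
#' unscaled median absolute deviation guarded against zero spread. The
#' tuning constant `c = 5` follows the Affymetrix biweight convention.
#'
#' @param values non-empty numeric vector.
#' @param c tuning constant (default 5).
#' @param eps relative guard added to the MAD scale (default 1e-4).
#' @param tol convergence tolerance on the location estimate.
#' @param max_iter iteration cap.
#' @return the biweight location, a single number. Equals the common value
#'   for a constant vector and the value itself for a singleton.
#' @export
tukey_biweight_mean <- function(values, c = 5, eps = 1e-4,
                                tol = 1e-9, max_iter = 100L) {
  if (!length(values)) stop("`values` must be non-empty")
  if (anyNA(values)) stop("`values` must not contain NA")
  if (length(values) == 1L) return(values[[1L]])
  t0 <- stats::median(values)
  s <- stats::mad(values, constant = 1) + eps * stats::median(abs(values))
  if (s == 0) return(t0)  # zero spread: all values equal
  for (i in seq_len(max_iter)) {
    u <- (values - t0) / (c * s)
    w <- (1 - u^2)^2
    w[abs(u) >= 1] <- 0
    if (all(w == 0)) return(t0)
    t1 <- sum(w * values) / sum(w)
    if (abs(t1 - t0) <= tol) return(t1)
    t0 <- t1
  }
  t0
}
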