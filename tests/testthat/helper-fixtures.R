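# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

# Tiny deterministic fold-change matrix with named genes/comparisons.
tiny_fcm <- function(n_genes = 6L, n_comps = 8L, n_studies = 4L, seed = 42L) {
  set.seed(seed)
  values <- matrix(rnorm(n_genes * n_comps), n_genes, n_comps,
                   dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                   sprintf("c%02d", seq_len(n_comps))))
  fold_change_matrix(values, sprintf("s%02d", rep_len(seq_len(n_studies), n_comps)))
}

# Matrix with exactly prescribed component variances (squared singular
# values), built from random orthonormal factors.
fcm_with_spectrum <- function(variances, n_genes = 8L, n_comps = 8L, seed = 1L) {
  set.seed(seed)
  r <- length(variances)
  u <- qr.Q(qr(matrix(rnorm(n_genes * r), n_genes, r)))
  v <- qr.Q(qr(matrix(rnorm(n_comps * r), n_comps, r)))
  values <- u %*% diag(sqrt(variances), r) %*% t(v)
  dimnames(values) <- list(sprintf("g%02d", seq_len(n_genes)),
                           sprintf("c%02d", seq_len(n_comps)))
  fold_change_matrix(values)
}

# Independent unweighted KS running-sum oracle (plain loop, weight p = 0).
brute_force_ks_es <- function(fold_changes, gene_set) {
  genes <- names(fold_changes)
  ord <- order(-fold_changes, genes)
  genes <- genes[ord]
  n_hit <- sum(genes %in% gene_set)
  n_miss <- length(genes) - n_hit
  running <- 0
  best <- 0
  for (g in genes) {
    running <- running + if (g %in% gene_set) 1 / n_hit else -1 / n_miss
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# Does a panel cover every pathway at level min(q, attainable)?
covers_all <- function(genes, pathways, q, universe) {
  all(vapply(pathways, function(s) {
    s <- intersect(s, universe)
    sum(s %in% genes) >= min(q, length(s))
  }, NA))
}

# Brute-force oracle: does ANY size-n subset of the universe cover all
# pathways at level q? (exhaustive enumeration; keep the universe small)
any_cover_exists <- function(pathways, universe, n, q) {
  if (n >= length(universe)) return(covers_all(universe, pathways, q, universe))
  subsets <- utils::combn(universe, n)
  for (j in seq_len(ncol(subsets)))
    if (covers_all(subsets[, j], pathways, q, universe)) return(TRUE)
  FALSE
}

# Random small pathway collection over a lettered universe.
random_small_collection <- function(n_genes, n_pathways, seed) {
  set.seed(seed)
  universe <- sprintf("x%02d", seq_len(n_genes))
  sets <- lapply(seq_len(n_pathways), function(i)
    sample(universe, sample(2:min(5, n_genes), 1)))
  names(sets) <- sprintf("P%d", seq_len(n_pathways))
  list(universe = universe, pathways = gene_set_collection(sets))
}

# Uniform random importance scores over a universe (for tie-break testing).
random_scores <- function(universe, seed) {
  set.seed(seed)
  stats::setNames(runif(length(universe)), universe)
}
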