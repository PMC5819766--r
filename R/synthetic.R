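#' Specification for a synthetic fold-change corpus
#'
#' Describes a corpus with planted co-expression structure: `n_modules`
#' gene modules, each loading on one latent eigengene factor (modules are
#' assigned to the `latent_rank` factors cyclically), remaining genes pure
#' noise, and comparisons grouped into studies whose factor intensities
#' differ — the study-to-study heterogeneity that experiment clustering
#' expects to find.
#'
#' @param n_genes total genes.
#' @param n_comparisons total comparisons (columns).
#' @param n_studies number of studies the comparisons are split across.
#' @param module_sizes integer vector of module sizes (its length is the
#'   module count; sum must not exceed `n_genes`).
#' @param latent_rank number of latent factors (defaults to the module
#'   count).
#' @param factor_scale standard deviation of the latent factor values.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param n_pathways number of synthetic gene sets to generate.
#' @param pathway_size_range integer length-2 vector: min/max pathway size.
#' @param pathway_module_alignment probability in [0, 1] that a pathway is
#'   anchored to one module rather than drawn uniformly.
#' @param study_effect_sd standard deviation (log scale) of per-study factor
#'   intensity multipliers; 0 removes study structure.
#' @param seed RNG seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 500L, n_comparisons = 200L,
                           n_studies = 40L, module_sizes = rep(30L, 5L),
                           latent_rank = length(module_sizes),
                           factor_scale = 1, noise_sd = 0.1,
                           n_pathways = 50L, pathway_size_range = c(5L, 20L),
                           pathway_module_alignment = 0.7,
                           study_effect_sd = 0.5, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_comparisons = as.integer(n_comparisons),
               n_studies = as.integer(n_studies),
               module_sizes = as.integer(module_sizes),
               latent_rank = as.integer(latent_rank),
               factor_scale = factor_scale, noise_sd = noise_sd,
               n_pathways = as.integer(n_pathways),
               pathway_size_range = as.integer(pathway_size_range),
               pathway_module_alignment = pathway_module_alignment,
               study_effect_sd = study_effect_sd, seed = as.integer(seed))
  if (sum(spec$module_sizes) > spec$n_genes)
    stop("module sizes sum to more than `n_genes`")
  if (length(spec$module_sizes) && spec$latent_rank < 1L)
    stop("`latent_rank` must be >= 1 when modules exist")
  if (spec$latent_rank > min(spec$n_genes, spec$n_comparisons))
    stop("`latent_rank` exceeds min(n_genes, n_comparisons)")
  if (spec$noise_sd < 0 || spec$factor_scale <= 0)
    stop("`factor_scale` must be positive and `noise_sd` non-negative")
  if (spec$pathway_module_alignment < 0 || spec$pathway_module_alignment > 1)
    stop("`pathway_module_alignment` must be in [0, 1]")
  if (spec$n_studies > spec$n_comparisons)
    stop("more studies than comparisons")
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a synthetic fold-change corpus with planted modules
#'
#' Fold changes are `loadings %*% t(factors) + noise`: module genes load on
#' their module's latent factor with magnitudes uniform on [0.5, 1.5] and
#' random signs (so absolute-correlation clustering must group
#' anti-correlated partners), non-module genes are pure Gaussian noise, and
#' each study modulates every factor by its own lognormal intensity
#' multiplier.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `fcm` (a [fold_change_matrix()]) and `truth` (list:
#'   `module` — module index per gene, NA outside modules; `factors` —
#'   comparisons x latent_rank matrix; `loadings`; `module_factor` — factor
#'   index per module; `module_genes` — list of gene ids per module).
#' @export
generate_foldchange_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    comps <- sprintf("C%04d", seq_len(spec$n_comparisons))
    studies <- sprintf("S%03d", rep_len(seq_len(spec$n_studies),
                                        spec$n_comparisons))
    n_modules <- length(spec$module_sizes)
    module <- rep(NA_integer_, spec$n_genes)
    if (n_modules)
      module[seq_len(sum(spec$module_sizes))] <-
        rep(seq_len(n_modules), spec$module_sizes)
    module_factor <- if (n_modules)
      rep_len(seq_len(spec$latent_rank), n_modules) else integer(0)
    loadings <- matrix(0, spec$n_genes, spec$latent_rank)
    for (b in seq_len(n_modules)) {
      idx <- which(module == b)
      loadings[idx, module_factor[b]] <-
        stats::runif(length(idx), 0.5, 1.5) *
        sample(c(-1, 1), length(idx), replace = TRUE)
    }
    intensity <- matrix(exp(stats::rnorm(spec$n_studies * spec$latent_rank,
                                         0, spec$study_effect_sd)),
                        spec$n_studies, spec$latent_rank)
    factors <- matrix(stats::rnorm(spec$n_comparisons * spec$latent_rank,
                                   0, spec$factor_scale),
                      spec$n_comparisons, spec$latent_rank) *
      intensity[rep_len(seq_len(spec$n_studies), spec$n_comparisons), ,
                drop = FALSE]
    values <- loadings %*% t(factors)
    if (spec$noise_sd > 0)
      values <- values + matrix(stats::rnorm(length(values), 0, spec$noise_sd),
                                nrow(values))
    dimnames(values) <- list(genes, comps)
    truth <- list(module = stats::setNames(module, genes),
                  factors = factors, loadings = loadings,
                  module_factor = module_factor,
                  module_genes = lapply(seq_len(n_modules),
                                        function(b) genes[which(module == b)]))
    list(fcm = fold_change_matrix(values, studies), truth = truth)
  })
}

#' Generate a synthetic pathway collection aligned with planted modules
#'
#' Each pathway is, with probability `pathway_module_alignment`, anchored to
#' one module: as many members as possible are drawn from the module's
#' genes, topped up uniformly from the rest. Otherwise members are drawn
#' uniformly from all genes. Sizes are uniform on `pathway_size_range`.
#'
#' @param truth ground-truth list from [generate_foldchange_corpus()].
#' @param spec the [synthetic_spec()] that produced the corpus.
#' @return a `gene_set_collection` of `n_pathways` sets; attribute
#'   `anchored_module` gives the anchor module index (NA for uniform
#'   pathways).
#' @export
generate_pathways <- function(truth, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- names(truth$module)
  lo <- spec$pathway_size_range[1L]; hi <- spec$pathway_size_range[2L]
  if (lo < 1L || hi < lo || hi > length(genes))
    stop("infeasible `pathway_size_range`")
  if (spec$n_pathways == 0L) return(gene_set_collection(list()))
  n_modules <- length(truth$module_genes)
  with_seed(spec$seed + 1L, {
    anchors <- rep(NA_integer_, spec$n_pathways)
    sets <- vector("list", spec$n_pathways)
    for (i in seq_len(spec$n_pathways)) {
      size <- if (lo == hi) lo else sample(seq(lo, hi), 1L)
      aligned <- n_modules > 0L &&
        stats::runif(1L) < spec$pathway_module_alignment
      if (aligned) {
        b <- sample.int(n_modules, 1L)
        anchors[i] <- b
        core <- sample(truth$module_genes[[b]],
                       min(size, length(truth$module_genes[[b]])))
        extra <- if (size > length(core))
          sample(setdiff(genes, core), size - length(core)) else character(0)
        sets[[i]] <- c(core, extra)
      } else {
        sets[[i]] <- sample(genes, size)
      }
    }
    names(sets) <- sprintf("PW%04d", seq_len(spec$n_pathways))
    out <- gene_set_collection(sets)
    attr(out, "anchored_module") <- anchors
    out
  })
}
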