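#' Pathway coverage report for a selection
#'
#' Summarises how well a gene panel represents a pathway collection:
#' per-pathway covered-gene counts and covered fractions, per selected gene
#' the number of pathways containing it (multiplicity), and collection-level
#' summaries.
#'
#' @param selection a `sentinel_selection` or a character vector of genes.
#' @param pathways a `gene_set_collection`.
#' @param q coverage level used for the `covered_at_q` summary (default 3).
#' @return list with `pathway` (data frame: name, size, covered, fraction),
#'   `gene_multiplicity` (named integer per selected gene), and `summary`
#'   (pathways covered at level >= q, mean/median coverage fraction, mean
#'   multiplicity).
#' @export
coverage_report <- function(selection, pathways, q = 3L) {
  genes <- if (inherits(selection, "sentinel_selection")) selection$genes
           else as.character(selection)
  covered <- vapply(pathways, function(s) sum(s %in% genes), 0L)
  size <- lengths(pathways)
  frac <- ifelse(size > 0, covered / size, 0)
  mult <- vapply(genes, function(g) sum(vapply(pathways, function(s) g %in% s, NA)), 0L)
  list(
    pathway = data.frame(name = names(pathways), size = as.integer(size),
                         covered = as.integer(covered), fraction = frac,
                         row.names = NULL, stringsAsFactors = FALSE),
    gene_multiplicity = mult,
    summary = list(
      n_pathways = length(pathways),
      covered_at_q = sum(covered >= pmin(q, size)),
      mean_fraction = if (length(pathways)) mean(frac) else NA_real_,
      median_fraction = if (length(pathways)) stats::median(frac) else NA_real_,
      mean_multiplicity = if (length(genes)) mean(mult) else NA_real_))
}

# Restrict a collection to a gene universe, dropping emptied pathways.
restrict_to_universe <- function(pathways, universe) {
  sets <- lapply(pathways, function(s) intersect(s, universe))
  keep <- lengths(sets) > 0L
  if (!all(keep))
    message(sum(!keep), " pathway(s) have no gene in the scoring universe; dropped")
  sets[keep]
}

#' Pathways not yet represented by q selected genes
#'
#' A pathway is uncovered while fewer than `min(q, attainable)` of its genes
#' are selected, where `attainable` is the number of its genes present in
#' the scoring universe: a pathway whose universe footprint is smaller than
#' `q` is considered covered once every attainable member is selected
#' (otherwise refinement could never terminate).
#'
#' @param selection a `sentinel_selection` or character vector.
#' @param pathways a `gene_set_collection`, already restricted (or not) to
#'   the universe.
#' @param q required representation level (default 3).
#' @param universe optional character vector of scorable genes; defaults to
#'   the union of all pathway genes and the selection.
#' @return character vector of uncovered pathway names.
#' @export
uncovered_pathways <- function(selection, pathways, q = 3L, universe = NULL) {
  if (q < 0L) stop("`q` must be >= 0")
  if (q == 0L) return(character(0))
  genes <- if (inherits(selection, "sentinel_selection")) selection$genes
           else as.character(selection)
  if (is.null(universe)) universe <- union(unlist(pathways, use.names = FALSE), genes)
  names(pathways)[vapply(pathways, function(s) {
    s <- intersect(s, universe)
    sum(s %in% genes) < min(q, length(s))
  }, NA)]
}

# OIS lookup helper: named numeric vector from an importance_scores object
# or a plain named vector; genes without a score get -Inf (never preferred).
ois_lookup <- function(scores, genes) {
  v <- if (inherits(scores, "importance_scores"))
    stats::setNames(scores$OIS, scores$gene) else scores
  out <- v[genes]
  out[is.na(out)] <- -Inf
  stats::setNames(as.numeric(out), genes)
}

#' Best inclusion candidate for coverage refinement
#'
#' The unselected universe gene contained in the largest number of uncovered
#' pathways; ties broken by higher OIS, then by ascending gene identifier.
#'
#' @param selection current `sentinel_selection` or character vector.
#' @param pathways a `gene_set_collection`.
#' @param q coverage level.
#' @param scores `importance_scores` (or named OIS vector) for tie-breaking.
#' @param universe character vector of selectable genes.
#' @return a single gene identifier, or `NA_character_` when no unselected
#'   gene touches an uncovered pathway.
#' @export
best_inclusion_candidate <- function(selection, pathways, q, scores,
                                     universe = NULL) {
  genes <- if (inherits(selection, "sentinel_selection")) selection$genes
           else as.character(selection)
  if (is.null(universe)) universe <- union(unlist(pathways, use.names = FALSE), genes)
  unc <- uncovered_pathways(genes, pathways, q, universe)
  if (!length(unc)) return(NA_character_)
  candidates <- setdiff(intersect(unique(unlist(pathways[unc], use.names = FALSE)),
                                  universe), genes)
  if (!length(candidates)) return(NA_character_)
  counts <- vapply(candidates, function(g)
    sum(vapply(pathways[unc], function(s) g %in% s, NA)), 0L)
  ois <- ois_lookup(scores, candidates)
  candidates[order(-counts, -ois, candidates)][1L]
}

#' Best exclusion candidate for coverage refinement
#'
#' Among selected genes whose removal would not drop any pathway below its
#' attainable coverage level, the one overlapping the fewest pathways, with
#' ties broken by smaller OIS, then ascending identifier.
#'
#' @inheritParams best_inclusion_candidate
#' @param q coverage level used for the removability check.
#' @param protect genes never eligible for exclusion (e.g. a gene just
#'   swapped in).
#' @return a single gene identifier, or `NA_character_` when nothing is
#'   removable.
#' @export
best_exclusion_candidate <- function(selection, pathways, scores, q = 3L,
                                     universe = NULL, protect = character(0)) {
  genes <- if (inherits(selection, "sentinel_selection")) selection$genes
           else as.character(selection)
  if (!length(genes)) stop("selection is empty")
  if (is.null(universe)) universe <- union(unlist(pathways, use.names = FALSE), genes)
  sets_u <- lapply(pathways, function(s) intersect(s, universe))
  covered_count <- vapply(sets_u, function(s) sum(s %in% genes), 0L)
  need <- pmin(q, lengths(sets_u))
  # a gene is removable when every pathway containing it keeps >= need members
  removable <- vapply(genes, function(g) {
    in_pw <- vapply(sets_u, function(s) g %in% s, NA)
    all(covered_count[in_pw] - 1L >= need[in_pw])
  }, NA)
  pool <- setdiff(genes[removable], protect)
  if (!length(pool)) return(NA_character_)
  mult <- vapply(pool, function(g) sum(vapply(sets_u, function(s) g %in% s, NA)), 0L)
  ois <- ois_lookup(scores, pool)
  pool[order(mult, ois, pool)][1L]
}

#' Refine a selection until every pathway is covered
#'
#' Greedy replacement: while uncovered pathways remain, swap in the gene
#' touching the most uncovered pathways and swap out the least connected,
#' lowest-scoring removable gene, keeping the panel size fixed. Genes swapped
#' in carry provenance `"coverage_replacement"`. Terminates when all
#' attainably-coverable pathways are covered, when a swap becomes
#' infeasible, or at `max_iter`; the residual uncovered list is attached
#' either way.
#'
#' @param initial a `sentinel_selection` (e.g. from [select_top_n()]).
#' @param pathways a `gene_set_collection`.
#' @param q required genes per pathway (default 3).
#' @param scores `importance_scores` (or named OIS vector) driving
#'   tie-breaks.
#' @param universe character vector of selectable genes (default: the genes
#'   scored); pathway membership is evaluated against it.
#' @param max_iter iteration cap (default 10000).
#' @return a `sentinel_selection` with extra fields `swap_log` (data frame
#'   of included/excluded genes per iteration) and `residual_uncovered`
#'   (character vector, empty on full coverage).
#' @export
refine_selection <- function(initial, pathways, q = 3L, scores,
                             universe = NULL, max_iter = 10000L) {
  stopifnot(inherits(initial, "sentinel_selection"))
  if (q < 1L) stop("`q` must be >= 1")
  if (is.null(universe)) {
    universe <- if (inherits(scores, "importance_scores")) scores$gene
                else names(scores)
    if (is.null(universe))
      universe <- union(unlist(pathways, use.names = FALSE), initial$genes)
  }
  genes <- initial$genes
  prov <- initial$provenance
  swaps <- list()
  residual <- character(0)
  for (it in seq_len(max_iter)) {
    unc <- uncovered_pathways(genes, pathways, q, universe)
    if (!length(unc)) break
    g_in <- best_inclusion_candidate(genes, pathways, q, scores, universe)
    if (is.na(g_in)) { residual <- unc; break }
    # removability is judged on the panel with the incoming gene added, so a
    # swap can never lose coverage the inclusion just bought
    g_out <- best_exclusion_candidate(c(genes, g_in), pathways, scores, q,
                                      universe, protect = g_in)
    if (is.na(g_out)) { residual <- unc; break }
    genes <- c(setdiff(genes, g_out), g_in)
    prov <- prov[names(prov) != g_out]
    prov[g_in] <- "coverage_replacement"
    swaps[[length(swaps) + 1L]] <- data.frame(iteration = it, included = g_in,
                                              excluded = g_out,
                                              stringsAsFactors = FALSE)
    if (it == max_iter)
      residual <- uncovered_pathways(genes, pathways, q, universe)
  }
  out <- sentinel_selection(genes, prov[genes],
                            parameters = c(initial$parameters, list(q = q)))
  out$swap_log <- if (length(swaps)) do.call(rbind, swaps)
                  else data.frame(iteration = integer(0), included = character(0),
                                  excluded = character(0), stringsAsFactors = FALSE)
  out$residual_uncovered <- residual
  if (length(residual))
    warning("refinement stopped with ", length(residual),
            " pathway(s) still uncovered")
  out
}

#' Merge nominated genes into a selection
#'
#' Appends user-nominated genes to a refined panel. Genes already selected
#' keep their original provenance; new genes are flagged `"nominated"` and
#' appended in nomination order.
#'
#' @param selection a `sentinel_selection`.
#' @param nominated ordered character vector of nominated gene ids.
#' @return the augmented `sentinel_selection`.
#' @export
merge_nominations <- function(selection, nominated) {
  stopifnot(inherits(selection, "sentinel_selection"))
  nominated <- unique(as.character(nominated))
  new <- setdiff(nominated, selection$genes)
  genes <- c(selection$genes, new)
  prov <- c(selection$provenance, stats::setNames(rep("nominated", length(new)), new))
  out <- sentinel_selection(genes, prov[genes], parameters = selection$parameters)
  out$swap_log <- selection$swap_log
  out$residual_uncovered <- selection$residual_uncovered
  out
}
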