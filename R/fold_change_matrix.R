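#' Fold-change matrix container
#'
#' A `fold_change_matrix` is the universal currency of the panel-design
#' pipeline: a numeric matrix of log2 fold changes with genes as rows and
#' treatment-vs-control comparisons as columns, plus one study label per
#' comparison. Comparisons from the same study (e.g. one GEO series) share a
#' label so that resampling schemes can operate at the study level.
#'
#' @param values numeric matrix, genes x comparisons, with unique non-empty
#'   row and column names and no missing entries.
#' @param study_ids character vector of study labels, one per comparison.
#'   Defaults to one study per comparison.
#' @return An object of class `fold_change_matrix`: the matrix with a
#'   `study_ids` attribute.
#' @export
fold_change_matrix <- function(values, study_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and comparison column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate comparison identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyNA(values))
    stop("fold-change matrix contains missing values; impute or drop ",
         "offending rows upstream")
  if (is.null(study_ids)) study_ids <- colnames(values)
  study_ids <- as.character(study_ids)
  if (length(study_ids) != ncol(values))
    stop("`study_ids` must have one entry per comparison")
  structure(values, study_ids = study_ids, class = c("fold_change_matrix", "matrix"))
}

#' @export
print.fold_change_matrix <- function(x, ...) {
  cat(sprintf("fold_change_matrix: %d genes x %d comparisons (%d studies)\n",
              nrow(x), ncol(x), length(unique(attr(x, "study_ids")))))
  invisible(x)
}

#' Study labels of a fold-change matrix
#' @param fcm a `fold_change_matrix`.
#' @return character vector, one study label per comparison.
#' @export
study_ids <- function(fcm) attr(fcm, "study_ids")

#' Subset a fold-change matrix by comparison
#'
#' Keeps the `fold_change_matrix` class and the matching study labels.
#'
#' @param fcm a `fold_change_matrix`.
#' @param comparisons column indices, names, or a logical mask.
#' @return a `fold_change_matrix` restricted to the requested comparisons.
#' @export
subset_comparisons <- function(fcm, comparisons) {
  idx <- seq_len(ncol(fcm))
  names(idx) <- colnames(fcm)
  if (is.character(comparisons)) comparisons <- idx[comparisons]
  if (is.logical(comparisons)) comparisons <- which(comparisons)
  fold_change_matrix(unclass(fcm)[, comparisons, drop = FALSE],
                     study_ids(fcm)[comparisons])
}

#' Subset a fold-change matrix by gene
#' @param fcm a `fold_change_matrix`.
#' @param genes row names or indices.
#' @return a `fold_change_matrix` restricted to the requested genes.
#' @export
subset_genes <- function(fcm, genes) {
  if (is.character(genes)) {
    missing <- setdiff(genes, rownames(fcm))
    if (length(missing))
      stop("genes absent from matrix: ", paste(missing, collapse = ", "))
  }
  fold_change_matrix(unclass(fcm)[genes, , drop = FALSE], study_ids(fcm))
}
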