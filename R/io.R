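#' Read a fold-change matrix from a tab-delimited file
#'
#' Expects a TSV with the first row holding comparison identifiers, the first
#' column holding gene identifiers, and a fully numeric body. Missing values
#' are rejected: the curation producing a fold-change corpus should leave
#' none, and silent imputation would distort every downstream score.
#'
#' @param path path to the TSV file.
#' @param study_map optional named character vector mapping comparison id to
#'   study label; comparisons absent from the map (or all of them, when the
#'   map is `NULL`) are treated as single-comparison studies.
#' @return a [fold_change_matrix()].
#' @export
read_fold_change_matrix <- function(path, study_map = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "", comment.char = "")
  gene_ids <- tab[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  body <- as.matrix(tab[, -1L, drop = FALSE])
  values <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing cell at gene '%s', comparison '%s' in %s",
                 gene_ids[bad[1L]], colnames(body)[bad[2L]], path))
  }
  dimnames(values) <- list(gene_ids, colnames(body))
  studies <- colnames(body)
  if (!is.null(study_map)) {
    hit <- colnames(body) %in% names(study_map)
    studies[hit] <- study_map[colnames(body)[hit]]
  }
  fold_change_matrix(values, studies)
}

#' Write a fold-change matrix as TSV
#'
#' @param fcm a [fold_change_matrix()].
#' @param path output path.
#' @param gene_column header for the gene-identifier column.
#' @return `path`, invisibly.
#' @export
write_fold_change_matrix <- function(fcm, path, gene_column = "gene") {
  df <- data.frame(rownames(fcm), unclass(fcm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- gene_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a treatment/control design table
#'
#' The design table pairs each comparison with its treatment and control
#' sample columns in a signal matrix. Layout: TSV with columns `Series`,
#' `ID`, `Samples_A` (treatment) and `Samples_B` (control), the sample lists
#' `;`-separated.
#'
#' @param path path to the design TSV.
#' @return a data frame with columns `series_id`, `comparison_id`,
#'   `treatment` and `control` (the last two are list columns of sample ids).
#' @export
read_design_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "", comment.char = "")
  required <- c("Series", "ID", "Samples_A", "Samples_B")
  if (!all(required %in% names(tab)))
    stop("design table must have columns ", paste(required, collapse = ", "))
  if (anyDuplicated(tab$ID))
    stop("duplicate comparison ids in design: ",
         paste(unique(tab$ID[duplicated(tab$ID)]), collapse = ", "))
  split_ids <- function(x) strsplit(x, ";", fixed = TRUE)
  out <- data.frame(series_id = tab$Series, comparison_id = tab$ID,
                    stringsAsFactors = FALSE)
  out$treatment <- lapply(split_ids(tab$Samples_A), function(v) v[nzchar(v)])
  out$control <- lapply(split_ids(tab$Samples_B), function(v) v[nzchar(v)])
  n_trt <- lengths(out$treatment); n_ctl <- lengths(out$control)
  if (any(n_trt == 0L) || any(n_ctl == 0L))
    stop("every design row needs >=1 treatment and >=1 control sample; ",
         "offending comparison(s): ",
         paste(out$comparison_id[n_trt == 0L | n_ctl == 0L], collapse = ", "))
  out
}

#' Compute log2 fold changes from a signal matrix and a design table
#'
#' For each comparison the fold change of a gene is the difference of
#' arithmetic means of its log2 signals: mean over treatment samples minus
#' mean over control samples (the standard limma-style contrast on
#' RMA-normalised data). Study labels come from the design's series column.
#'
#' @param signal numeric matrix of log2 signal, genes x samples, with row and
#'   column names.
#' @param design a design data frame as returned by [read_design_table()].
#' @return a [fold_change_matrix()] with one column per design row.
#' @export
compute_fold_changes <- function(signal, design) {
  if (is.null(rownames(signal)) || is.null(colnames(signal)))
    stop("`signal` must carry gene row names and sample column names")
  cols <- lapply(seq_len(nrow(design)), function(i) {
    trt <- design$treatment[[i]]; ctl <- design$control[[i]]
    missing <- setdiff(c(trt, ctl), colnames(signal))
    if (length(missing))
      stop(sprintf("unknown sample id(s) %s in comparison '%s'",
                   paste(missing, collapse = ", "), design$comparison_id[i]))
    rowMeans(signal[, trt, drop = FALSE]) - rowMeans(signal[, ctl, drop = FALSE])
  })
  values <- do.call(cbind, cols)
  dimnames(values) <- list(rownames(signal), design$comparison_id)
  fold_change_matrix(values, design$series_id)
}

#' Collapse probe-level rows to gene-level rows by averaging
#'
#' Convenience utility for matrices still indexed by probe set: rows mapping
#' to the same gene are averaged (log-scale mean). Probes absent from the map
#' are dropped.
#'
#' @param values numeric matrix with probe row names.
#' @param probe_map named character vector, probe id -> gene id.
#' @return numeric matrix with gene row names.
#' @export
collapse_probes <- function(values, probe_map) {
  keep <- rownames(values) %in% names(probe_map)
  values <- values[keep, , drop = FALSE]
  genes <- probe_map[rownames(values)]
  out <- rowsum(values, group = genes)
  counts <- table(genes)
  out / as.vector(counts[rownames(out)])
}

#' Read a GMT gene-set collection
#'
#' One pathway per line: name, description, then one or more gene symbols,
#' tab-delimited (the MSigDB distribution format). Duplicate genes within a
#' line are collapsed; membership is case-sensitive.
#'
#' @param path path to the GMT file.
#' @return a named list of character vectors of gene ids, with a
#'   `descriptions` attribute; class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields in ", path)
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_))
    stop("duplicate pathway name(s) in ", path, ": ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  gene_set_collection(sets, vapply(fields, `[[`, "", 2L))
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (pathway name -> gene ids).
#' @param descriptions optional character vector of per-pathway descriptions.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stop("pathway names must be present and unique")
    if (any(lengths(sets) == 0L)) stop("every gene set must be non-empty")
    sets <- lapply(sets, function(s) unique(as.character(s)))
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d pathways, median size %s\n",
              length(x),
              if (length(x)) stats::median(lengths(x)) else "NA"))
  invisible(x)
}

#' Write a gene-set collection to GMT
#' @param sets a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines and `#` comments are ignored;
#' duplicates are dropped with a warning, preserving first-occurrence order.
#'
#' @param path path to the list file.
#' @return character vector of unique gene identifiers.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (anyDuplicated(lines))
    warning("dropping ", sum(duplicated(lines)), " duplicate entries in ", path)
  unique(lines)
}

#' Write an importance-score table as TSV
#'
#' Columns: gene, DIS, CIS, rank_DIS, rank_CIS, OIS and (when a selection is
#' supplied) a 0/1 selected flag.
#'
#' @param scores an `importance_scores` object (see [compute_ois()]).
#' @param path output path.
#' @param selection optional `sentinel_selection`; marks selected genes.
#' @return `path`, invisibly.
#' @export
write_scores_table <- function(scores, path, selection = NULL) {
  df <- as.data.frame(scores)
  if (!is.null(selection)) df$selected <- as.integer(df$gene %in% selection$genes)
  utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an importance-score table written by [write_scores_table()]
#' @param path path to the TSV.
#' @return an `importance_scores` object.
#' @export
read_scores_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  structure(list(gene = as.character(df$gene), DIS = df$DIS, CIS = df$CIS,
                 rank_DIS = as.integer(df$rank_DIS),
                 rank_CIS = as.integer(df$rank_CIS),
                 OIS = df$OIS, N = nrow(df)),
            class = "importance_scores")
}

#' Serialize / restore an extrapolation model
#'
#' Round-trips the model object (sentinel order, loadings, coefficients and
#' the composed extrapolation matrix) bit-identically through a single-file
#' RDS container.
#'
#' @param model an `extrapolation_model` (see [fit_extrapolation()]).
#' @param path file path.
#' @return `path` (save) or the restored model (load).
#' @export
save_extrapolation_model <- function(model, path) {
  stopifnot(inherits(model, "extrapolation_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_extrapolation_model
#' @export
load_extrapolation_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "extrapolation_model"))
    stop("file does not contain an extrapolation model: ", path)
  model
}
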