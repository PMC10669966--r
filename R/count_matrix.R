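#' Gene-by-sample count matrix with subtype labels
#'
#' The pipeline's main data carrier: a non-negative integer matrix of read
#' counts (genes in rows, samples in columns) together with a subtype label
#' for every sample.
#'
#' @param counts integer matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids).
#' @param groups named character vector or factor mapping sample id to
#'   subtype label; names must cover every column of `counts`. An unnamed
#'   vector of `ncol(counts)` labels in column order is also accepted.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `groups` (factor, one level per subtype, aligned
#'   with the columns of `counts`).
#' @export
count_matrix <- function(counts, groups) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("`counts` must have rownames (gene ids)")
  }
  if (is.null(colnames(counts))) {
    stop("`counts` must have colnames (sample ids)")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(is.na(counts))) stop("counts contain NA")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "double" # large library sizes overflow int sums

  grp <- groups
  if (!is.null(names(grp))) {
    missing <- setdiff(colnames(counts), names(grp))
    if (length(missing)) {
      stop("no group label for sample(s): ", paste(missing, collapse = ", "))
    }
    grp <- grp[colnames(counts)]
  } else if (length(grp) != ncol(counts)) {
    stop("`groups` must be named by sample id or have one label per column")
  }
  grp <- factor(as.character(grp))
  names(grp) <- colnames(counts)

  structure(list(counts = counts, groups = grp), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d genes x %d samples\n",
    nrow(x$counts), ncol(x$counts)
  ))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix
#'
#' @param x a [count_matrix()].
#' @param genes,samples index vectors (ids, positions or logical) selecting
#'   rows and columns; missing means keep all.
#' @param ... unused.
#' @return A `count_matrix` restricted to the selected genes and samples.
#' @export
`[.count_matrix` <- function(x, genes, samples, ...) {
  if (missing(genes)) genes <- seq_len(nrow(x$counts))
  if (missing(samples)) samples <- seq_len(ncol(x$counts))
  cts <- x$counts[genes, samples, drop = FALSE]
  count_matrix(cts, droplevels(x$groups[colnames(cts)]))
}

#' Library sizes (column sums) of a count matrix
#'
#' @param x a [count_matrix()] or plain matrix.
#' @return Named numeric vector of per-sample total counts.
#' @export
library_sizes <- function(x) {
  cts <- if (inherits(x, "count_matrix")) x$counts else x
  colSums(cts)
}

#' Write counts and sample metadata as TSV
#'
#' Counts are written genes x samples with a leading `gene_id` column; the
#' metadata table has columns `sample_id` and `subtype`.
#'
#' @param x a [count_matrix()].
#' @param counts_path,meta_path output file paths.
#' @return Invisibly, `x`.
#' @export
write_count_matrix <- function(x, counts_path, meta_path) {
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample_id = names(x$groups),
                     subtype = as.character(x$groups),
                     stringsAsFactors = FALSE)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read counts and sample metadata written by [write_count_matrix()]
#'
#' @param counts_path,meta_path input file paths.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, meta_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cts <- as.matrix(df[, -1, drop = FALSE])
  rownames(cts) <- df[[1]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  groups <- stats::setNames(meta$subtype, meta$sample_id)
  count_matrix(cts, groups)
}
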