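#' Counts per million, linear or log2
#'
#' Linear mode returns `count / library_size * 1e6`. Log mode returns
#' `log2((count + pr) / (library_size + 2 * pr) * 1e6)` where
#' `pr = prior_count * library_size / mean(library_size)` is the
#' library-size-adjusted prior that keeps the offset proportional to depth,
#' so samples with equal depth and equal counts map to equal values and
#' zeros never hit `log(0)`.
#'
#' @param x a [count_matrix()] or numeric matrix of counts.
#' @param log logical; return log2 values?
#' @param prior_count prior added before the log (log mode only).
#' @return Numeric matrix, genes x samples.
#' @export
cpm <- function(x, log = FALSE, prior_count = 2) {
  cts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  lib <- colSums(cts)
  if (any(lib <= 0)) {
    bad <- colnames(cts)[lib <= 0]
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "))
  }
  if (!log) {
    return(sweep(cts, 2, lib, "/") * 1e6)
  }
  pr <- prior_count * lib / mean(lib)
  num <- sweep(cts, 2, pr, "+")
  den <- lib + 2 * pr
  log2(sweep(num, 2, den, "/") * 1e6)
}

#' Sample QC by median log-CPM deviation
#'
#' Computes each sample's median log-CPM over all genes, the median M of
#' those per-sample medians, and drops every sample whose relative
#' deviation `|median_s - M| / |M|` exceeds `threshold`.
#'
#' @param x a [count_matrix()].
#' @param threshold maximum tolerated relative deviation (default 0.10).
#' @param prior_count prior passed to [cpm()].
#' @return List with `kept` (filtered `count_matrix`) and `report`, a
#'   data frame with one row per input sample: `sample_id`,
#'   `median_logcount`, `deviation`, `excluded`.
#' @export
filter_samples_by_median_logcount <- function(x, threshold = 0.10,
                                              prior_count = 2) {
  stopifnot(inherits(x, "count_matrix"))
  if (ncol(x$counts) < 2) stop("need at least 2 samples")
  lcpm <- cpm(x, log = TRUE, prior_count = prior_count)
  med <- apply(lcpm, 2, stats::median)
  M <- stats::median(med)
  if (M == 0) stop("median of per-sample medians is 0; relative deviation undefined")
  dev <- abs(med - M) / abs(M)
  excluded <- dev > threshold
  report <- data.frame(
    sample_id = colnames(x$counts),
    median_logcount = unname(med),
    deviation = unname(dev),
    excluded = unname(excluded),
    stringsAsFactors = FALSE
  )
  attr(report, "overall_median") <- M
  attr(report, "threshold") <- threshold
  kept <- x[, !excluded]
  list(kept = kept, report = report)
}

#' Gene filtering by expression level
#'
#' Keeps a gene when it is expressed at a usable level in at least as many
#' samples as the smallest subtype group: the gene must have
#' CPM >= `min_count / median(library sizes) * 1e6` in at least
#' `min(table(groups))` samples, and a total count across samples of at
#' least `min_total_count`.
#'
#' @param x a [count_matrix()].
#' @param min_count minimum count at the median library size (default 10).
#' @param min_total_count minimum total count over all samples (default 15).
#' @return Character vector of kept gene ids, in input order.
#' @export
filter_genes_by_expression <- function(x, min_count = 10,
                                       min_total_count = 15) {
  stopifnot(inherits(x, "count_matrix"))
  if (min_count < 0 || min_total_count < 0) stop("filter parameters must be >= 0")
  n_min <- min(table(x$groups))
  k <- min_count / stats::median(library_sizes(x)) * 1e6
  cp <- cpm(x, log = FALSE)
  keep <- rowSums(cp >= k) >= n_min & rowSums(x$counts) >= min_total_count
  rownames(x$counts)[keep]
}

#' Write a sample QC report as TSV
#'
#' @param report the report data frame from
#'   [filter_samples_by_median_logcount()].
#' @param path output file path.
#' @return Invisibly, `report`.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(report)
}
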