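#' Per-tissue mean expression summaries from a compendium
#'
#' The compendium is a sample-level expression table: one row per sample
#' with a tissue label and a healthy/cancer category, and one column per
#' gene. For each tissue the per-gene mean is computed over non-missing
#' values; a gene's mean is reported only where the tissue holds at least
#' `min_datapoints` non-missing values for it.
#'
#' @param compendium data frame with columns `sample_id`, `tissue`,
#'   `category` (values `"healthy"` or `"cancer"`) followed by one numeric
#'   column per gene. Missing values allowed.
#' @param min_datapoints minimum non-missing values per (gene, tissue)
#'   required to report a mean (default 6).
#' @return A list of tissue summaries. Each element (named by tissue) is a
#'   list with `tissue`, `category`, `means` (named numeric vector over the
#'   genes that passed the datapoint rule) and `n_datapoints` (named integer
#'   vector over all genes).
#' @export
summarize_tissues <- function(compendium, min_datapoints = 6) {
  meta_cols <- c("sample_id", "tissue", "category")
  if (!all(meta_cols %in% names(compendium))) {
    stop("compendium must have columns sample_id, tissue, category")
  }
  bad <- setdiff(unique(compendium$category), c("healthy", "cancer"))
  if (length(bad)) {
    stop("unknown category label(s): ", paste(bad, collapse = ", "))
  }
  gene_cols <- setdiff(names(compendium), meta_cols)
  out <- list()
  for (tis in unique(compendium$tissue)) {
    rows <- compendium[compendium$tissue == tis, , drop = FALSE]
    cat_lab <- unique(rows$category)
    if (length(cat_lab) != 1) {
      stop("tissue ", tis, " has inconsistent category labels")
    }
    vals <- as.matrix(rows[, gene_cols, drop = FALSE])
    n_ok <- colSums(!is.na(vals))
    means <- colMeans(vals, na.rm = TRUE)
    keep <- n_ok >= min_datapoints
    out[[tis]] <- list(
      tissue = tis,
      category = cat_lab,
      means = means[keep],
      n_datapoints = n_ok
    )
  }
  out
}

#' Top-k genes of a tissue summary
#'
#' Genes are ranked by descending mean expression; ties are broken by
#' ascending gene id so the list is platform-independent. If fewer than `k`
#' genes carry a mean, the list is shorter.
#'
#' @param summary one element of the list returned by [summarize_tissues()].
#' @param k list length (default 500).
#' @return List with `tissue`, `category` and `genes` (character vector,
#'   length <= k).
#' @export
top_k <- function(summary, k = 500) {
  if (k <= 0) stop("k must be positive")
  if (!length(summary$means)) stop("summary carries no gene means")
  ord <- order(-summary$means, names(summary$means))
  genes <- names(summary$means)[ord]
  list(
    tissue = summary$tissue,
    category = summary$category,
    genes = utils::head(genes, k)
  )
}

#' Build a tissue-specificity exclusion list from top-k lists
#'
#' A gene enters the exclusion list when it appears in at least one top
#' list, in at most `max_healthy` healthy-tissue top lists and at most
#' `max_cancer` cancer-tissue top lists. Such genes are specific to few
#' tissues elsewhere and are removed from subtype DEG lists downstream.
#' Setting `invert = TRUE` instead excludes genes appearing in MORE than
#' `max_healthy` healthy or MORE than `max_cancer` cancer top lists
#' (broadly expressed genes); this variant is offered for exploration only.
#'
#' @param top_lists list of top lists from [top_k()].
#' @param max_healthy maximum healthy-tissue memberships (default 1).
#' @param max_cancer maximum cancer-tissue memberships (default 3).
#' @param invert use the complementary rule (default FALSE).
#' @return An object of class `exclusion_list`: list with `genes`
#'   (character, sorted), `healthy_count` and `cancer_count` (named integer
#'   vectors over the union of all top lists) and `params`.
#' @export
build_exclusion_list <- function(top_lists, max_healthy = 1, max_cancer = 3,
                                 invert = FALSE) {
  if (max_healthy < 0 || max_cancer < 0) stop("membership caps must be >= 0")
  healthy <- unlist(lapply(top_lists, function(tl) {
    if (identical(tl$category, "healthy")) tl$genes else character()
  }), use.names = FALSE)
  cancer <- unlist(lapply(top_lists, function(tl) {
    if (identical(tl$category, "cancer")) tl$genes else character()
  }), use.names = FALSE)
  universe <- sort(unique(c(healthy, cancer)))
  h_cnt <- table(factor(healthy, levels = universe))
  c_cnt <- table(factor(cancer, levels = universe))
  h_cnt <- stats::setNames(as.integer(h_cnt), universe)
  c_cnt <- stats::setNames(as.integer(c_cnt), universe)
  keep <- if (invert) {
    h_cnt > max_healthy | c_cnt > max_cancer
  } else {
    h_cnt <= max_healthy & c_cnt <= max_cancer
  }
  structure(list(
    genes = universe[keep],
    healthy_count = h_cnt,
    cancer_count = c_cnt,
    params = list(max_healthy = max_healthy, max_cancer = max_cancer,
                  invert = invert)
  ), class = "exclusion_list")
}

#' @export
print.exclusion_list <- function(x, ...) {
  cat(sprintf(
    "exclusion_list: %d genes (of %d top-list members); max_healthy=%d, max_cancer=%d%s\n",
    length(x$genes), length(x$healthy_count),
    x$params$max_healthy, x$params$max_cancer,
    if (isTRUE(x$params$invert)) " [inverted rule]" else ""
  ))
  invisible(x)
}

#' Remove exclusion-list members from a gene list
#'
#' @param genes character vector of gene ids.
#' @param exclusion an [build_exclusion_list()] result, or a character
#'   vector of gene ids to exclude.
#' @return `genes` with exclusion-list members removed, order preserved.
#' @export
apply_exclusion <- function(genes, exclusion) {
  excl <- if (inherits(exclusion, "exclusion_list")) exclusion$genes else exclusion
  genes[!genes %in% excl]
}

#' Build an exclusion list straight from a compendium table
#'
#' Convenience wrapper chaining [summarize_tissues()], [top_k()] and
#' [build_exclusion_list()].
#'
#' @inheritParams summarize_tissues
#' @inheritParams top_k
#' @inheritParams build_exclusion_list
#' @return An `exclusion_list`.
#' @export
exclusion_list_from_compendium <- function(compendium, min_datapoints = 6,
                                           k = 500, max_healthy = 1,
                                           max_cancer = 3, invert = FALSE) {
  summaries <- summarize_tissues(compendium, min_datapoints = min_datapoints)
  summaries <- Filter(function(s) length(s$means) > 0, summaries)
  tls <- lapply(summaries, top_k, k = k)
  build_exclusion_list(tls, max_healthy = max_healthy,
                       max_cancer = max_cancer, invert = invert)
}

#' Write an exclusion list as TSV (gene, healthy_count, cancer_count)
#'
#' Rows cover the listed genes only; counts are the top-list memberships
#' that admitted each gene.
#'
#' @param x an `exclusion_list`.
#' @param path output file path.
#' @return Invisibly, `x`.
#' @export
write_exclusion_list <- function(x, path) {
  df <- data.frame(
    gene = x$genes,
    healthy_count = unname(x$healthy_count[x$genes]),
    cancer_count = unname(x$cancer_count[x$genes]),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read an exclusion list written by [write_exclusion_list()]
#'
#' @param path input file path.
#' @return A character vector of excluded gene ids with the membership
#'   counts attached as attributes.
#' @export
read_exclusion_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(df$gene,
            healthy_count = stats::setNames(df$healthy_count, df$gene),
            cancer_count = stats::setNames(df$cancer_count, df$gene))
}
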