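#' Read a gene-set library in GMT format
#'
#' GMT is tab-separated: set name, description, then member genes, one set
#' per line. Duplicate members within a set are dropped with a warning.
#'
#' @param path path to a GMT file.
#' @return An object of class `gene_set_library`: list with `sets` (named
#'   list of character vectors) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("malformed GMT line ", i, ": need name, description and >= 1 gene")
    }
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate members in set '", parts[1], "' (line ", i,
              "); deduplicated")
      genes <- unique(genes)
    }
    sets[[parts[1]]] <- genes
    descriptions[parts[1]] <- parts[2]
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_library")
}

#' Write a gene-set library in GMT format
#'
#' Round-trips with [read_gmt()].
#'
#' @param library a `gene_set_library` (or named list of gene vectors).
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_gmt <- function(library, path) {
  sets <- if (inherits(library, "gene_set_library")) library$sets else library
  descriptions <- if (inherits(library, "gene_set_library")) {
    library$descriptions
  } else {
    stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set over-representation by the hypergeometric test
#'
#' For each set, the one-sided Fisher exact p-value of the query/set
#' overlap: the hypergeometric upper tail of drawing at least the observed
#' overlap when `|query|` genes are sampled from a background of
#' `background` genes containing the set. p-values are BH-adjusted over
#' all sets in the library.
#'
#' @param query character vector of gene ids (e.g. a DEG list).
#' @param library a `gene_set_library` from [read_gmt()].
#' @param background background universe size (integer), or a character
#'   vector of background gene ids. Query genes outside the background are
#'   dropped with a warning (set `on_missing = "error"` to fail instead).
#' @param on_missing `"drop"` (default) or `"error"`.
#' @return Data frame with one row per set, sorted by ascending p then set
#'   name: `set`, `set_size`, `overlap`, `overlap_genes`
#'   (comma-separated), `odds_ratio`, `p`, `adjusted_p`.
#' @export
enrich <- function(query, library, background,
                   on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(library, "gene_set_library"))
  query <- unique(query)
  if (!length(query)) stop("query is empty")
  if (is.character(background)) {
    missing <- setdiff(query, background)
    if (length(missing)) {
      if (on_missing == "error") {
        stop(length(missing), " query gene(s) absent from background")
      }
      warning(length(missing), " query gene(s) absent from background; dropped")
      query <- setdiff(query, missing)
      if (!length(query)) stop("no query genes left after dropping")
    }
    bg_genes <- unique(background)
    N <- length(bg_genes)
    sets <- lapply(library$sets, intersect, bg_genes)
  } else {
    N <- as.integer(background)
    sets <- library$sets
  }
  if (N < length(query)) stop("background smaller than query")

  q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- sets[[nm]]
    m <- length(members)
    ov <- intersect(query, members)
    k <- length(ov)
    p <- stats::phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    # odds ratio of the 2x2 overlap table (0.5 continuity only when needed)
    a <- k; b <- q - k; c_ <- m - k; d <- N - m - b
    or <- if (b == 0 || c_ == 0) {
      (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c_ + 0.5))
    } else {
      a * d / (b * c_)
    }
    data.frame(set = nm, set_size = m, overlap = k,
               overlap_genes = paste(sort(ov), collapse = ","),
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adjusted_p <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$set), ]
  rownames(res) <- NULL
  res
}
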