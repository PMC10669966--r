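#' Rescale counts to a common library size
#'
#' The conditional exact test assumes every sample has the same sequencing
#' depth. Counts are rescaled toward the geometric mean library size by
#' mean-preserving scaling, `count * common / observed`, rounded to the
#' nearest integer (deterministic default) or by seeded stochastic rounding.
#' Equal input library sizes return the counts unchanged.
#'
#' @param x a [count_matrix()].
#' @param rounding `"deterministic"` (round to nearest) or `"stochastic"`
#'   (round up with probability equal to the fractional part).
#' @param seed RNG seed used only for stochastic rounding.
#' @param lib_sizes optional effective library sizes overriding the column
#'   sums (e.g. column sums times [median_ratio_factors()]).
#' @return A `count_matrix` of adjusted counts with the common size stored
#'   in attribute `"common_size"`.
#' @export
equalize_library_sizes <- function(x, rounding = c("deterministic", "stochastic"),
                                   seed = 1L, lib_sizes = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  rounding <- match.arg(rounding)
  lib <- if (is.null(lib_sizes)) library_sizes(x) else lib_sizes
  if (any(lib <= 0)) stop("library sizes must be positive")
  common <- exp(mean(log(lib)))
  if (all(lib == lib[1])) {
    out <- x
    attr(out, "common_size") <- unname(lib[1])
    return(out)
  }
  scaled <- sweep(x$counts, 2, common / lib, "*")
  adj <- if (rounding == "deterministic") {
    round(scaled)
  } else {
    with_seed(seed, {
      fl <- floor(scaled)
      fl + (matrix(stats::runif(length(scaled)), nrow(scaled)) < (scaled - fl))
    })
  }
  out <- count_matrix(adj, x$groups)
  attr(out, "common_size") <- common
  out
}

#' Median-ratio normalization factors
#'
#' Each sample's sequencing depth is first re-estimated as the median,
#' over genes with all-positive counts, of the ratio of the sample's count
#' to the gene's geometric mean across samples (robust to a minority of
#' very highly expressed genes inflating the column sum). The returned
#' factor is that depth divided by the column sum, rescaled to geometric
#' mean 1, so `column sums * factors` gives composition-corrected
#' effective library sizes. Off by default throughout the DE path.
#'
#' @param x a [count_matrix()].
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
median_ratio_factors <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  cts <- x$counts
  pos <- rowSums(cts == 0) == 0
  if (!any(pos)) stop("no gene with all-positive counts; cannot normalize")
  logc <- log(cts[pos, , drop = FALSE])
  ref <- rowMeans(logc)
  depth <- exp(apply(logc - ref, 2, stats::median))
  f <- depth / colSums(cts)
  f / exp(mean(log(f)))
}

# Negative-binomial conditional log-likelihood per gene, summed over groups,
# given the per-group totals; counts assumed on equalized library sizes.
# For a group of n iid NB(mu, phi) observations with r = 1/phi,
#   P(y_1..y_n | sum = s) = prod C(y_i + r - 1, y_i) / C(s + n r - 1, s),
# which is free of mu. Returns a length-G vector for a single phi.
.cond_ll <- function(counts, groups, phi) {
  r <- 1 / phi
  A <- lgamma(counts + r) - lgamma(counts + 1)
  ll <- rowSums(A) - ncol(counts) * lgamma(r)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    n <- length(idx)
    s <- rowSums(counts[, idx, drop = FALSE])
    ll <- ll - (lgamma(s + n * r) - lgamma(n * r) - lgamma(s + 1))
  }
  ll
}

#' Common dispersion by conditional maximum likelihood
#'
#' Maximizes the sum over genes of the negative-binomial conditional
#' log-likelihood given per-group totals, computed on library-size
#' equalized counts. The search is bracketed on `[1e-6, 10]` (log scale).
#'
#' @param x a [count_matrix()] (equalized internally via
#'   [equalize_library_sizes()] unless `equalize = FALSE`).
#' @param equalize equalize library sizes first? Default TRUE.
#' @return The common dispersion estimate (positive scalar).
#' @export
estimate_common_dispersion <- function(x, equalize = TRUE) {
  stopifnot(inherits(x, "count_matrix"))
  if (!any(table(x$groups) >= 2)) {
    stop("no group with >= 2 samples; dispersion is not estimable")
  }
  if (equalize) x <- equalize_library_sizes(x)
  obj <- function(lphi) sum(.cond_ll(x$counts, x$groups, exp(lphi)))
  opt <- stats::optimize(obj, interval = log(c(1e-6, 10)), maximum = TRUE,
                         tol = 1e-8)
  exp(opt$maximum)
}

#' Tagwise dispersions by weighted-likelihood shrinkage
#'
#' Each gene's dispersion maximizes its own conditional log-likelihood plus
#' `prior_df / 2` times the average conditional log-likelihood over all
#' genes (whose maximizer is the common dispersion). Small `prior_df` lets
#' genes follow their own data; `prior_df -> Inf` returns the common value
#' for every gene.
#'
#' @param x a [count_matrix()] (equalized internally unless
#'   `equalize = FALSE`).
#' @param phi_common common dispersion; estimated with
#'   [estimate_common_dispersion()] when NULL.
#' @param prior_df prior degrees of freedom controlling shrinkage
#'   (default 10).
#' @param equalize equalize library sizes first? Default TRUE.
#' @return Named numeric vector of per-gene dispersions.
#' @export
estimate_tagwise_dispersion <- function(x, phi_common = NULL, prior_df = 10,
                                        equalize = TRUE) {
  stopifnot(inherits(x, "count_matrix"))
  if (equalize) x <- equalize_library_sizes(x)
  if (is.null(phi_common)) {
    phi_common <- estimate_common_dispersion(x, equalize = FALSE)
  }
  if (phi_common <= 0) stop("phi_common must be positive")
  counts <- x$counts
  groups <- x$groups
  G <- nrow(counts)

  # log2-spaced grid around the common value, densified near it so the
  # shared-likelihood spline places its peak accurately
  steps <- sort(unique(c(seq(-8, 8, by = 0.5), seq(-0.5, 0.5, by = 0.05))))
  phis <- pmin(pmax(phi_common * 2^steps, 1e-8), 50)
  phis <- sort(unique(phis))
  llmat <- vapply(phis, function(p) .cond_ll(counts, groups, p), numeric(G))
  if (G == 1) llmat <- matrix(llmat, nrow = 1)
  shared <- colMeans(llmat)
  shared_fun <- stats::splinefun(log(phis), shared, method = "natural")

  wl <- llmat + (prior_df / 2) * rep(shared, each = G)
  best <- max.col(wl, ties.method = "first")
  lo <- log(phis[pmax(best - 1L, 1L)])
  hi <- log(phis[pmin(best + 1L, length(phis))])

  out <- numeric(G)
  for (g in seq_len(G)) {
    yg <- counts[g, , drop = FALSE]
    obj <- function(lphi) {
      .cond_ll(yg, groups, exp(lphi)) + (prior_df / 2) * shared_fun(lphi)
    }
    if (lo[g] >= hi[g]) {
      out[g] <- exp(lo[g])
    } else {
      opt <- stats::optimize(obj, interval = c(lo[g], hi[g]), maximum = TRUE,
                             tol = 1e-9)
      out[g] <- exp(opt$maximum)
    }
  }
  stats::setNames(out, rownames(counts))
}
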