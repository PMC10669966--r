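# Independent brute-force oracles. These restate the rules directly, in
# plain loops with their own probability formulas, and never call the
# implementation paths they check.

# NB pmf via explicit log-gamma formula (size r, mean mu), avoiding dnbinom
oracle_nb_pmf <- function(y, r, mu) {
  p <- r / (r + mu)
  exp(lgamma(y + r) - lgamma(r) - lgamma(y + 1) + r * log(p) + y * log1p(-p))
}

# direct-summation conditional exact test: enumerate all splits of S
oracle_nb_exact <- function(s_A, s_B, n_A, n_B, phi) {
  S <- s_A + s_B
  if (S == 0) return(1)
  mu <- S / (n_A + n_B)
  probs <- vapply(0:S, function(a) {
    oracle_nb_pmf(a, n_A / phi, n_A * mu) *
      oracle_nb_pmf(S - a, n_B / phi, n_B * mu)
  }, numeric(1))
  probs <- probs / sum(probs)
  obs <- probs[s_A + 1]
  sum(probs[probs <= obs * (1 + 1e-10)])
}

# sample-exclusion rule recomputed sentence-by-sentence
oracle_sample_filter <- function(cm, threshold = 0.10, prior_count = 2) {
  cts <- cm$counts
  lib <- colSums(cts)
  meds <- numeric(ncol(cts))
  for (s in seq_len(ncol(cts))) {
    pr <- prior_count * lib[s] / mean(lib)
    lcpm <- log2((cts[, s] + pr) / (lib[s] + 2 * pr) * 1e6)
    meds[s] <- median(lcpm)
  }
  M <- median(meds)
  keep <- abs(meds - M) / abs(M) <= threshold
  colnames(cts)[keep]
}

# gene-expression filter recomputed per gene
oracle_gene_filter <- function(cm, min_count = 10, min_total_count = 15) {
  cts <- cm$counts
  lib <- colSums(cts)
  k <- min_count / median(lib) * 1e6
  n_min <- min(table(cm$groups))
  kept <- character()
  for (g in seq_len(nrow(cts))) {
    cpm_g <- cts[g, ] / lib * 1e6
    if (sum(cpm_g >= k) >= n_min && sum(cts[g, ]) >= min_total_count) {
      kept <- c(kept, rownames(cts)[g])
    }
  }
  kept
}

# exclusion list recomputed from a compendium by plain set algebra
oracle_exclusion <- function(compendium, min_datapoints = 6, k = 500,
                             max_healthy = 1, max_cancer = 3) {
  gene_cols <- setdiff(names(compendium), c("sample_id", "tissue", "category"))
  top_lists <- list()
  for (tis in unique(compendium$tissue)) {
    rows <- compendium[compendium$tissue == tis, gene_cols, drop = FALSE]
    means <- c()
    for (g in gene_cols) {
      v <- rows[[g]]
      v <- v[!is.na(v)]
      if (length(v) >= min_datapoints) means[g] <- mean(v)
    }
    if (!length(means)) next
    ord <- order(-means, names(means))
    top_lists[[tis]] <- list(
      category = compendium$category[compendium$tissue == tis][1],
      genes = names(means)[ord][seq_len(min(k, length(means)))]
    )
  }
  universe <- unique(unlist(lapply(top_lists, `[[`, "genes")))
  excluded <- character()
  for (g in universe) {
    H <- sum(vapply(top_lists, function(tl) {
      tl$category == "healthy" && g %in% tl$genes
    }, logical(1)))
    C <- sum(vapply(top_lists, function(tl) {
      tl$category == "cancer" && g %in% tl$genes
    }, logical(1)))
    if (H <= max_healthy && C <= max_cancer) excluded <- c(excluded, g)
  }
  sort(excluded)
}

# a small random compendium with missing values, healthy + cancer tissues
random_compendium <- function(seed, n_tissues = 8, n_genes = 100,
                              max_samples = 9) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  n_healthy <- sample(1:(n_tissues - 1), 1)
  cat_lab <- rep(c("healthy", "cancer"), c(n_healthy, n_tissues - n_healthy))
  rows <- list()
  for (ti in seq_len(n_tissues)) {
    n <- sample(2:max_samples, 1)
    vals <- matrix(rnorm(n * n_genes, 5, 2), nrow = n,
                   dimnames = list(NULL, genes))
    vals[runif(length(vals)) < 0.1] <- NA
    rows[[ti]] <- data.frame(
      sample_id = sprintf("t%02d_s%d", ti, seq_len(n)),
      tissue = sprintf("t%02d", ti), category = cat_lab[ti], vals,
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# a small count_matrix with uneven library sizes
random_count_matrix <- function(seed, n_genes = 120, group_sizes = c(A = 8, B = 6)) {
  set.seed(seed)
  subtype <- rep(names(group_sizes), group_sizes)
  ids <- paste0(subtype, seq_along(subtype))
  base <- 2^runif(n_genes, 0, 8)
  depth <- runif(length(ids), 0.5, 2)
  mu <- outer(base, depth)
  cts <- matrix(rnbinom(length(mu), mu = mu, size = 5), nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)), ids))
  count_matrix(cts, setNames(subtype, ids))
}

# number of r x c tables with the given margins, by direct expansion
oracle_count_tables <- function(rs, cs) {
  r <- length(rs)
  grids <- expand.grid(rep(list(0:max(cs)), (r - 1) * (length(cs) - 1)))
  # only feasible for tiny margins; build tables cell by cell
  count <- 0
  apply(grids, 1, function(v) {
    m <- matrix(0, r, length(cs))
    m[seq_len(r - 1), seq_len(length(cs) - 1)] <- matrix(v, r - 1)
    m[r, seq_len(length(cs) - 1)] <- cs[seq_len(length(cs) - 1)] -
      colSums(m[seq_len(r - 1), seq_len(length(cs) - 1), drop = FALSE])
    m[, length(cs)] <- rs - rowSums(m[, seq_len(length(cs) - 1), drop = FALSE])
    if (all(m >= 0)) count <<- count + 1
    NULL
  })
  count
}
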