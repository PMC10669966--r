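#' Immunohistochemistry H-score
#'
#' Staining intensity (0-3) times percentage of positive cells (0-100),
#' giving a score in [0, 300]. Vectorized.
#'
#' @param intensity integer staining intensity in 0..3.
#' @param percent_positive percent positive cells in [0, 100] (fractional
#'   values allowed).
#' @return Numeric H-score(s) in [0, 300].
#' @export
h_score <- function(intensity, percent_positive) {
  if (any(intensity != round(intensity)) || any(intensity < 0) ||
      any(intensity > 3)) {
    stop("intensity must be an integer in 0..3")
  }
  if (any(percent_positive < 0) || any(percent_positive > 100)) {
    stop("percent_positive must lie in [0, 100]")
  }
  intensity * percent_positive
}

#' Bin H-scores into quartile classes and a low/high split
#'
#' Quartile classes use the closed ranges 0-75, 76-150, 151-225, 226-300
#' with boundaries belonging to the lower class; the binary split is low
#' for H-scores up to 150, high above. Fractional scores strictly between
#' a boundary and the next integer (e.g. 75.5) fall in the upper class.
#'
#' @param h numeric H-score(s) in [0, 300].
#' @return Data frame with columns `quartile` (integer 0-3) and `binary`
#'   (`"low"` or `"high"`).
#' @export
h_score_bins <- function(h) {
  if (any(h < 0) || any(h > 300)) stop("H-score must lie in [0, 300]")
  quartile <- ifelse(h <= 75, 0L, ifelse(h <= 150, 1L, ifelse(h <= 225, 2L, 3L)))
  data.frame(quartile = quartile,
             binary = ifelse(h <= 150, "low", "high"),
             stringsAsFactors = FALSE)
}

#' Pearson chi-square test of independence for an r x c table
#'
#' The classical uncorrected statistic `sum((O - E)^2 / E)` with
#' `(r - 1)(c - 1)` degrees of freedom; no continuity correction is
#' applied.
#'
#' @param table non-negative integer matrix, at least 2 x 2.
#' @return List with `statistic`, `df` and `p`.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stop("table must be at least 2 x 2")
  if (any(table < 0)) stop("counts must be non-negative")
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column margin")
  N <- sum(table)
  E <- outer(rs, cs) / N
  stat <- sum((table - E)^2 / E)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Exact Fisher-Freeman-Halton test for an r x c table
#'
#' Generalizes Fisher's exact test to arbitrary r x c tables: the p-value
#' sums the multivariate hypergeometric probabilities of every table with
#' the observed margins whose probability does not exceed the observed
#' table's probability (relative tie tolerance 1e-7). Tables are
#' enumerated by recursive traversal with margin bounds; the final free
#' row is evaluated vectorized. When the enumeration budget is exceeded,
#' a seeded Monte-Carlo version (Patefield sampling via [r2dtable()]) is
#' available through `method = "monte.carlo"`.
#'
#' @param table non-negative integer matrix, at least 2 x 2.
#' @param method `"exact"` (default) or `"monte.carlo"`.
#' @param max_tables enumeration budget for the exact method (default
#'   5e6 tables).
#' @param B number of Monte-Carlo tables (default 1e5).
#' @param seed RNG seed for the Monte-Carlo method.
#' @param tie_tol relative tolerance for probability ties (default 1e-7).
#' @return List with `p`, `method`, and for the exact method `n_tables`
#'   (tables enumerated) and `total_prob` (their probability sum, a
#'   self-check that should be 1).
#' @export
fisher_freeman_halton <- function(table, method = c("exact", "monte.carlo"),
                                  max_tables = 5e6, B = 1e5, seed = 1L,
                                  tie_tol = 1e-7) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stop("table must be at least 2 x 2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  rs <- rowSums(table)
  cs <- colSums(table)
  N <- sum(table)
  logconst <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  logp_obs <- logconst - sum(lgamma(table + 1))
  thresh <- logp_obs + log1p(tie_tol)

  if (method == "monte.carlo") {
    sims <- with_seed(seed, stats::r2dtable(B, rs, cs))
    logp_sim <- vapply(sims, function(m) logconst - sum(lgamma(m + 1)),
                       numeric(1))
    p <- (1 + sum(logp_sim <= thresh)) / (B + 1)
    return(list(p = p, method = "monte.carlo", B = B))
  }

  r <- nrow(table)
  cc <- ncol(table)
  env <- new.env()
  env$p_le <- 0
  env$tot <- 0
  env$count <- 0

  # finish the last free row (row r - 1) vectorized over its final free
  # cell; row r is then forced by the column remainders
  finish <- function(rowleft, colrem, negsum) {
    lo <- max(0, rowleft - colrem[cc])
    hi <- min(rowleft, colrem[cc - 1])
    if (lo > hi) return()
    a <- lo:hi
    b <- rowleft - a
    fixed <- if (cc > 2) sum(lgamma(colrem[1:(cc - 2)] + 1)) else 0
    negs <- negsum + lgamma(a + 1) + lgamma(b + 1) + fixed +
      lgamma(colrem[cc - 1] - a + 1) + lgamma(colrem[cc] - b + 1)
    logp <- logconst - negs
    env$count <- env$count + length(a)
    if (env$count > max_tables) {
      stop("enumeration budget exceeded (", max_tables,
           " tables); use method = \"monte.carlo\"")
    }
    env$tot <- env$tot + sum(exp(logp))
    env$p_le <- env$p_le + sum(exp(logp[logp <= thresh]))
  }

  fill_row <- function(i, colrem, negsum) {
    rowtot <- rs[i]
    fill_cell <- function(j, rowleft, colrem, negsum) {
      if (i == r - 1 && j == cc - 1) {
        finish(rowleft, colrem, negsum)
        return()
      }
      if (j == cc) {
        # last cell of a non-final row is forced
        if (rowleft > colrem[cc]) return()
        colrem[cc] <- colrem[cc] - rowleft
        fill_row(i + 1, colrem, negsum + lgamma(rowleft + 1))
        return()
      }
      tail_cap <- sum(colrem[(j + 1):cc])
      lo <- max(0, rowleft - tail_cap)
      hi <- min(rowleft, colrem[j])
      if (lo > hi) return()
      for (a in lo:hi) {
        cr <- colrem
        cr[j] <- cr[j] - a
        fill_cell(j + 1, rowleft - a, cr, negsum + lgamma(a + 1))
      }
    }
    fill_cell(1, rowtot, colrem, negsum)
  }

  fill_row(1, cs, 0)
  list(p = min(env$p_le, 1), method = "exact",
       n_tables = env$count, total_prob = env$tot)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact distribution for small samples without ties, tie-corrected normal
#' approximation otherwise (via [stats::wilcox.test()]).
#'
#' @param x,y numeric samples.
#' @param correct continuity correction in the normal approximation
#'   (default TRUE).
#' @param exact force (TRUE/FALSE) or auto-select (NULL) the exact
#'   distribution.
#' @return List with `U` and `p`.
#' @export
mann_whitney_u <- function(x, y, correct = TRUE, exact = NULL) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, correct = correct, exact = exact)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Kruskal-Wallis test with optional Bonferroni-corrected pairwise tests
#'
#' Tie-corrected H statistic against the chi-square distribution with
#' k - 1 df; pairwise comparisons are Mann-Whitney tests with p-values
#' multiplied by the number of pairs (capped at 1).
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @param pairwise also compute pairwise comparisons? Default FALSE.
#' @return List with `H`, `df`, `p` and (when requested) `pairwise`, a
#'   symmetric matrix of Bonferroni-corrected p-values.
#' @export
kruskal_wallis <- function(groups, pairwise = FALSE) {
  if (length(groups) < 2 || any(!lengths(groups))) {
    stop("need >= 2 non-empty groups")
  }
  kt <- stats::kruskal.test(groups)
  out <- list(H = unname(kt$statistic), df = unname(kt$parameter),
              p = kt$p.value)
  if (pairwise) {
    k <- length(groups)
    nm <- names(groups)
    if (is.null(nm)) nm <- paste0("group", seq_len(k))
    n_pairs <- k * (k - 1) / 2
    mat <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        p <- mann_whitney_u(groups[[i]], groups[[j]])$p
        mat[i, j] <- mat[j, i] <- min(1, p * n_pairs)
      }
    }
    out$pairwise <- mat
  }
  out
}

#' Spearman or Pearson correlation with p-value
#'
#' Spearman's rho is Pearson's correlation on mid-ranks with the p-value
#' from the t transform `t = rho * sqrt((n - 2) / (1 - rho^2))`; Pearson
#' uses the same transform on the raw values.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param method `"spearman"` or `"pearson"`.
#' @return List with `estimate` and `p`.
#' @export
correlations <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  if (method == "spearman") {
    xr <- rank(x)
    yr <- rank(y)
  } else {
    xr <- x
    yr <- y
  }
  rho <- stats::cor(xr, yr)
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(estimate = rho, p = p)
}

#' Delta-delta-Ct relative expression for one measurement
#'
#' `dCt = mean(target Ct) - mean(reference Ct)` over the finite triplicate
#' values; relative expression is `2^-(dCt - calibrator_delta_ct)`. The
#' calibrator sample itself therefore maps to 1.
#'
#' @param target_ct,reference_ct Ct triplicates (numeric; at least one
#'   finite value each).
#' @param calibrator_delta_ct the calibrator sample's dCt.
#' @return Relative expression (positive scalar).
#' @export
delta_delta_ct <- function(target_ct, reference_ct, calibrator_delta_ct) {
  if (!any(is.finite(target_ct)) || !any(is.finite(reference_ct))) {
    stop("triplicate with no finite Ct value")
  }
  dct <- mean(target_ct[is.finite(target_ct)]) -
    mean(reference_ct[is.finite(reference_ct)])
  2^(-(dct - calibrator_delta_ct))
}

#' Delta-delta-Ct over a qPCR table
#'
#' Applies [delta_delta_ct()] to every sample of a table in the layout of
#' [simulate_qpcr()], using the `is_calibrator` row(s) to fix the
#' calibrator dCt (averaged when replicated).
#'
#' @param qpcr data frame with columns `sample_id`, `target_ct_1..3`,
#'   `reference_ct_1..3`, `is_calibrator`.
#' @return Data frame with columns `sample_id`, `delta_ct`,
#'   `relative_expression`.
#' @export
delta_delta_ct_table <- function(qpcr) {
  tcols <- paste0("target_ct_", 1:3)
  rcols <- paste0("reference_ct_", 1:3)
  stopifnot(all(c(tcols, rcols, "sample_id", "is_calibrator") %in% names(qpcr)))
  dct_row <- function(i) {
    tc <- as.numeric(qpcr[i, tcols])
    rc <- as.numeric(qpcr[i, rcols])
    if (!any(is.finite(tc)) || !any(is.finite(rc))) {
      stop("triplicate with no finite Ct value in sample ", qpcr$sample_id[i])
    }
    mean(tc[is.finite(tc)]) - mean(rc[is.finite(rc)])
  }
  dct <- vapply(seq_len(nrow(qpcr)), dct_row, numeric(1))
  cal <- mean(dct[qpcr$is_calibrator])
  if (!is.finite(cal)) stop("no calibrator row")
  keep <- !qpcr$is_calibrator
  data.frame(
    sample_id = qpcr$sample_id[keep],
    delta_ct = dct[keep],
    relative_expression = 2^(-(dct[keep] - cal)),
    stringsAsFactors = FALSE
  )
}

# pooled or Welch two-sample two-tailed t-test that tolerates zero variance
.t_test2 <- function(x, y, var_equal = TRUE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need >= 2 values per group")
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    return(list(t = if (m1 == m2) 0 else Inf * sign(m1 - m2),
                df = df, p = if (m1 == m2) 1 else 0))
  }
  tt <- (m1 - m2) / se
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Relative cell viability from a luminescence plate
#'
#' Subtracts the mean medium-background luminescence from every well,
#' divides by the mean background-subtracted control signal and scales to
#' percent, so the control mean maps to 100%. Each treatment is compared
#' with the control by a two-tailed unpaired t-test (pooled variance by
#' default, Welch by flag).
#'
#' @param plate data frame with columns `well`, `treatment`,
#'   `luminescence`, as produced by [simulate_viability_plate()].
#' @param control treatment label of the control wells (default
#'   `"control"`).
#' @param background treatment label of the medium-background wells
#'   (default `"background"`; if absent, no background is subtracted).
#' @param var_equal pooled-variance t-test (default TRUE); FALSE for
#'   Welch.
#' @return List with `per_well` (well, treatment, percent viability) and
#'   `summary` (treatment, mean percent, p vs control; NA for the control
#'   row).
#' @export
relative_viability <- function(plate, control = "control",
                               background = "background", var_equal = TRUE) {
  stopifnot(all(c("well", "treatment", "luminescence") %in% names(plate)))
  if (!any(plate$treatment == control)) stop("no control wells")
  bg <- if (any(plate$treatment == background)) {
    mean(plate$luminescence[plate$treatment == background])
  } else 0
  adj <- plate$luminescence - bg
  ctrl <- adj[plate$treatment == control]
  if (mean(ctrl) <= 0) stop("control mean <= 0 after background subtraction")
  keep <- plate$treatment != background
  pct <- adj[keep] / mean(ctrl) * 100
  per_well <- data.frame(well = plate$well[keep],
                         treatment = plate$treatment[keep],
                         percent_viability = pct,
                         stringsAsFactors = FALSE)
  treatments <- unique(per_well$treatment)
  ctrl_pct <- per_well$percent_viability[per_well$treatment == control]
  summary <- do.call(rbind, lapply(treatments, function(tr) {
    vals <- per_well$percent_viability[per_well$treatment == tr]
    p <- if (tr == control) NA_real_ else {
      .t_test2(vals, ctrl_pct, var_equal = var_equal)$p
    }
    data.frame(treatment = tr, mean_percent = mean(vals), p_vs_control = p,
               stringsAsFactors = FALSE)
  }))
  list(per_well = per_well, summary = summary)
}
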