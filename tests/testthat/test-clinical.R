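test_that("H-score is the intensity-percent product with range validation", {
  expect_equal(h_score(3, 100), 300)
  expect_equal(h_score(0, 80), 0)
  expect_equal(h_score(2, 60), 120)
  expect_equal(h_score(c(1, 2), c(10.5, 0)), c(10.5, 0))
  expect_error(h_score(4, 50), "0..3")
  expect_error(h_score(1.5, 50), "0..3")
  expect_error(h_score(2, 101), "0, 100")
})

test_that("H-score bins use closed boundaries and partition [0, 300]", {
  expect_equal(h_score_bins(150)$quartile, 1L)
  expect_equal(h_score_bins(150)$binary, "low")
  expect_equal(h_score_bins(151)$quartile, 2L)
  expect_equal(h_score_bins(151)$binary, "high")
  expect_equal(h_score_bins(300)$quartile, 3L)
  expect_equal(h_score_bins(75.5)$quartile, 1L) # fractional: above 75 is upper
  expect_error(h_score_bins(301), "0, 300")

  # every value lands in exactly one quartile and one binary class
  grid <- seq(0, 300, by = 0.25)
  bins <- h_score_bins(grid)
  expect_true(all(bins$quartile %in% 0:3))
  expect_true(all(bins$binary %in% c("low", "high")))
  expect_true(all(diff(bins$quartile) >= 0))
  expect_setequal(unique(bins$quartile), 0:3)
  expect_identical(bins$binary == "low", bins$quartile <= 1)
})

test_that("Pearson chi-square matches closed forms and rejects zero margins", {
  prop <- matrix(c(10, 20, 30, 60), 2, 2, byrow = TRUE)
  res <- pearson_chi_square(prop)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  perfect <- matrix(c(10, 0, 0, 10), 2, 2)
  expect_equal(pearson_chi_square(perfect)$statistic, 20)

  expect_error(pearson_chi_square(matrix(c(1, 0, 2, 0), 2, 2)), "margin")
  expect_error(pearson_chi_square(matrix(1:3, 1)), "2 x 2")
})

test_that("FFH equals the classical Fisher exact test on 2x2 tables", {
  set.seed(71)
  for (i in 1:25) {
    m <- matrix(rpois(4, 8), 2, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    got <- fisher_freeman_halton(m)
    expect_equal(got$p, fisher.test(m)$p.value, tolerance = 1e-9)
    expect_equal(got$total_prob, 1, tolerance = 1e-9)
  }
})

test_that("FFH enumeration is exhaustive and its probabilities sum to one", {
  m <- matrix(c(3, 1, 2, 2, 1, 3), 3, 2, byrow = TRUE)
  got <- fisher_freeman_halton(m)
  expect_equal(got$n_tables, oracle_count_tables(rowSums(m), colSums(m)))
  expect_equal(got$total_prob, 1, tolerance = 1e-9)

  m2 <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3, 3)
  got2 <- fisher_freeman_halton(m2)
  expect_equal(got2$n_tables, oracle_count_tables(rowSums(m2), colSums(m2)))
  expect_equal(got2$total_prob, 1, tolerance = 1e-9)
})

test_that("FFH exact and chi-square p agree on large balanced 2x2 tables", {
  m <- matrix(c(120, 80, 90, 110), 2, 2, byrow = TRUE)
  exact <- fisher_freeman_halton(m)$p
  asym <- pearson_chi_square(m)$p
  expect_lt(abs(exact - asym), 0.01)
})

test_that("FFH budget errors advise Monte-Carlo, which approximates the exact p", {
  m <- matrix(c(3, 1, 2, 2, 1, 3), 3, 2, byrow = TRUE)
  expect_error(fisher_freeman_halton(m, max_tables = 3), "monte.carlo")
  exact <- fisher_freeman_halton(m)$p
  mc <- fisher_freeman_halton(m, method = "monte.carlo", B = 20000, seed = 5)
  expect_lt(abs(mc$p - exact), 0.02)
  mc2 <- fisher_freeman_halton(m, method = "monte.carlo", B = 20000, seed = 5)
  expect_identical(mc$p, mc2$p)
})

test_that("FFH is invariant to row and column permutations", {
  m <- matrix(c(8, 2, 3, 7, 5, 5), 3, 2, byrow = TRUE)
  p0 <- fisher_freeman_halton(m)$p
  expect_equal(fisher_freeman_halton(m[c(2, 3, 1), ])$p, p0, tolerance = 1e-12)
  expect_equal(fisher_freeman_halton(m[, 2:1])$p, p0, tolerance = 1e-12)
})

test_that("Mann-Whitney has the documented exact values and invariances", {
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p, 0.9)
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 0.1)
  # invariant to monotone transforms of the pooled data
  x <- c(3, 9, 15, 2)
  y <- c(7, 11, 4)
  expect_equal(mann_whitney_u(exp(x / 4), exp(y / 4))$p,
               mann_whitney_u(x, y)$p)
  expect_error(mann_whitney_u(numeric(), y), "non-empty")
})

test_that("Kruskal-Wallis reduces correctly and pairwise tests are Bonferroni-scaled", {
  same <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)

  set.seed(72)
  x <- rnorm(30)
  y <- rnorm(30, 1)
  kw <- kruskal_wallis(list(x = x, y = y))
  mw <- mann_whitney_u(x, y, correct = FALSE, exact = FALSE)
  expect_equal(kw$p, mw$p, tolerance = 1e-10)

  three <- kruskal_wallis(list(x = x, y = y, z = rnorm(30, 2)),
                          pairwise = TRUE)
  expect_equal(dim(three$pairwise), c(3, 3))
  raw_xy <- mann_whitney_u(x, y)$p
  expect_equal(three$pairwise["x", "y"], min(1, raw_xy * 3))
  expect_true(all(three$pairwise[upper.tri(three$pairwise)] <= 1))
})

test_that("correlations behave on exact monotone and linear relationships", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(correlations(x, x)$estimate, 1)
  expect_equal(correlations(x, -x)$estimate, -1)
  cub <- correlations(x, x^3, method = "spearman")
  expect_equal(cub$estimate, 1)
  expect_lt(correlations(x, x^3, method = "pearson")$estimate, 1)
  expect_error(correlations(x, rep(1, 5)), "constant")
  expect_error(correlations(1:2, 1:2), "n >= 3")
  # p-value via the t transform matches cor.test for pearson
  set.seed(73)
  a <- rnorm(20)
  b <- a + rnorm(20)
  expect_equal(correlations(a, b, method = "pearson")$p,
               cor.test(a, b)$p.value, tolerance = 1e-12)
})

test_that("delta-delta-Ct has its closed-form fixed points", {
  expect_equal(delta_delta_ct(c(22, 22, 22), c(20, 20, 20), 2), 1)
  expect_equal(delta_delta_ct(c(20, 20, 20), c(20, 20, 20), 2), 4)
  expect_equal(delta_delta_ct(c(21, NA, 21), c(20, 20, NA), 1), 1)
  expect_error(delta_delta_ct(c(NA, NA, NA), c(20, 20, 20), 1), "finite")
})

test_that("relative viability normalizes to control and flags degenerate plates", {
  plate <- data.frame(
    well = sprintf("w%02d", 1:24),
    treatment = rep(c("background", "control", "drug"), each = 8),
    luminescence = c(rep(1000, 8), rep(21000, 8), rep(11000, 8))
  )
  rv <- relative_viability(plate)
  expect_equal(rv$summary$mean_percent[rv$summary$treatment == "drug"], 50)
  expect_equal(rv$summary$mean_percent[rv$summary$treatment == "control"], 100)
  expect_true(is.na(rv$summary$p_vs_control[rv$summary$treatment == "control"]))
  expect_equal(rv$summary$p_vs_control[rv$summary$treatment == "drug"], 0)

  # identical treatment and control -> 100% and p = 1
  plate$luminescence[17:24] <- 21000
  rv2 <- relative_viability(plate)
  expect_equal(rv2$summary$mean_percent[rv2$summary$treatment == "drug"], 100)
  expect_equal(rv2$summary$p_vs_control[rv2$summary$treatment == "drug"], 1)

  bad <- plate
  bad$luminescence[9:16] <- 500
  expect_error(relative_viability(bad), "control mean")
  expect_error(relative_viability(plate[1:8, ]), "no control")
})

test_that("Welch and pooled t-tests are both available and sensible", {
  set.seed(74)
  plate <- simulate_viability_plate("drug", c(drug = 0.7), seed = 7)
  pooled <- relative_viability(plate, var_equal = TRUE)
  welch <- relative_viability(plate, var_equal = FALSE)
  pp <- pooled$summary$p_vs_control[pooled$summary$treatment == "drug"]
  pw <- welch$summary$p_vs_control[welch$summary$treatment == "drug"]
  expect_lt(pp, 0.001)
  expect_lt(pw, 0.001)
})
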