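test_that("count simulation is a pure function of its spec and seed", {
  spec <- simulation_spec(n_genes = 50, group_sizes = c(A = 3, B = 4),
                          seed = 7)
  a <- simulate_subtype_counts(spec)
  b <- simulate_subtype_counts(spec)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)

  # and does not disturb the caller's RNG stream
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_subtype_counts(spec))
  expect_identical(runif(1), before)
})

test_that("planted genes with zero effect leave the ground truth empty", {
  planted <- data.frame(gene = c("gene_00001", "gene_00002"),
                        subtype = "A", effect = 0)
  spec <- simulation_spec(n_genes = 10, group_sizes = c(A = 2, B = 2),
                          planted_degs = planted, seed = 1)
  expect_equal(nrow(simulate_subtype_counts(spec)$truth), 0)
})

test_that("simulation specs reject invalid parameters", {
  expect_error(simulation_spec(dispersion = 0), "dispersion")
  expect_error(simulation_spec(group_sizes = c(A = 1, B = 5)), ">= 2")
  expect_error(simulation_spec(group_sizes = c(5, 5)), "named")
  expect_error(
    simulation_spec(n_genes = 5, group_sizes = c(A = 2, B = 2),
                    planted_degs = data.frame(gene = "nope", subtype = "A",
                                              effect = 1)),
    "universe")
  expect_error(
    simulation_spec(n_genes = 5, group_sizes = c(A = 2, B = 2),
                    planted_degs = data.frame(gene = "gene_00001",
                                              subtype = "C", effect = 1)),
    "subtype")
  expect_error(
    simulation_spec(n_genes = 5, group_sizes = c(A = 2, B = 2),
                    planted_degs = data.frame(gene = rep("gene_00001", 2),
                                              subtype = "A", effect = 1)),
    "unique")
})

test_that("null-gene moments match the generative NB(mu, mu + phi mu^2)", {
  # degenerate baseline range and fixed depth make mu = 16 for every gene
  genes <- sprintf("gene_%05d", 1:1200)
  planted <- data.frame(gene = genes[1:100], subtype = "B", effect = 3)
  spec <- simulation_spec(
    n_genes = 1200, group_sizes = c(A = 30, B = 30, C = 30),
    baseline_log_mean_range = c(4, 4), dispersion = 0.1,
    planted_degs = planted, library_size_range = c(1e6, 1e6), seed = 5
  )
  sim <- simulate_subtype_counts(spec)
  null_counts <- sim$counts$counts[-(1:100), ]
  mu <- 16
  v <- mu + 0.1 * mu^2
  n <- length(null_counts)
  expect_lt(abs(mean(null_counts) - mu), 3 * sqrt(v / n))
  expect_lt(abs(var(as.vector(null_counts)) / v - 1), 0.1)
  # planted genes are shifted only in their subtype
  planted_B <- sim$counts$counts[1:100, sim$counts$groups == "B"]
  planted_A <- sim$counts$counts[1:100, sim$counts$groups == "A"]
  expect_gt(mean(planted_B) / mean(planted_A), 6)
})

test_that("compendium construction guarantees top-list membership", {
  genes <- sprintf("gene_%05d", 1:200)
  ts <- list(gene_00150 = "healthy_01")
  spec <- compendium_spec(
    genes = genes, n_healthy_tissues = 6, n_cancer_tissues = 4,
    samples_per_tissue = 8, housekeeping_genes = genes[1:5],
    tissue_specific_genes = ts, seed = 3
  )
  cmp <- simulate_compendium(spec)
  summaries <- summarize_tissues(cmp, min_datapoints = 6)
  tls <- lapply(summaries, top_k, k = 10)
  for (tl in tls) {
    expect_true(all(genes[1:5] %in% tl$genes))
    expect_equal("gene_00150" %in% tl$genes, tl$tissue == "healthy_01")
  }
})

test_that("tissues below the datapoint minimum contribute no means", {
  spec <- compendium_spec(genes = sprintf("gene_%05d", 1:20),
                          n_healthy_tissues = 2, n_cancer_tissues = 1,
                          samples_per_tissue = 4, seed = 2)
  cmp <- simulate_compendium(spec)
  summaries <- summarize_tissues(cmp, min_datapoints = 6)
  expect_true(all(vapply(summaries, function(s) length(s$means) == 0,
                         logical(1))))
})

test_that("compendium spec validates gene and tissue references", {
  expect_error(compendium_spec(genes = c("a", "b"),
                               housekeeping_genes = "zz"), "universe")
  expect_error(compendium_spec(genes = c("a", "b"),
                               tissue_specific_genes = list(a = "mars")),
               "tissue label")
})

test_that("IHC generator is seeded and degenerate distributions give H = 0", {
  tab <- simulate_ihc_table(40, hscore_params = list(DDLPS = c(0, 0),
                                                     MLPS = c(0, 0),
                                                     PLPS = c(0, 0)),
                            seed = 4)
  expect_true(all(tab$h_score == 0))
  expect_true(all(tab$intensity == 0))
  a <- simulate_ihc_table(25, seed = 9)
  b <- simulate_ihc_table(25, seed = 9)
  expect_identical(a, b)
  expect_true(all(tab$intensity %in% 0:3))
  expect_true(all(a$percent_positive >= 0 & a$percent_positive <= 100))
  expect_equal(a$h_score, a$intensity * a$percent_positive)
})

test_that("null sex association in IHC tables gives uniform chi-square p", {
  ps <- vapply(1:250, function(i) {
    tab <- simulate_ihc_table(200, seed = 1000 + i)
    cls <- h_score_bins(tab$h_score)$binary
    ct <- table(tab$sex, cls)
    pearson_chi_square(ct)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("qPCR round-trips truth exactly at zero noise and in mean with noise", {
  q1 <- simulate_qpcr(5, true_relative_expression = 1, ct_noise_sd = 0, seed = 1)
  r1 <- delta_delta_ct_table(q1)
  expect_equal(r1$relative_expression, rep(1, 5))
  q4 <- simulate_qpcr(5, true_relative_expression = 4, ct_noise_sd = 0, seed = 1)
  expect_equal(delta_delta_ct_table(q4)$relative_expression, rep(4, 5))
  # noisy: mean recovered log2 expression within its Monte-Carlo CI
  q <- simulate_qpcr(50, true_relative_expression = 4, ct_noise_sd = 0.2,
                     seed = 12)
  lg <- log2(delta_delta_ct_table(q)$relative_expression)
  se <- sd(lg) / sqrt(length(lg))
  expect_lt(abs(mean(lg) - 2), 4 * se + 4 * 0.2 / sqrt(3))
})

test_that("viability plates recover planted effects", {
  pl <- simulate_viability_plate("drug", c(drug = 0.5), noise_sd = 0, seed = 1)
  rv <- relative_viability(pl)
  expect_equal(rv$summary$mean_percent[rv$summary$treatment == "drug"], 50)
  expect_equal(rv$summary$mean_percent[rv$summary$treatment == "control"], 100)
  pl1 <- simulate_viability_plate("drug", c(drug = 1), noise_sd = 0, seed = 1)
  rv1 <- relative_viability(pl1)
  expect_equal(rv1$per_well$percent_viability,
               rep(100, nrow(rv1$per_well)))
  # power: a 50% effect at typical noise is detected at p < 0.001
  ps <- vapply(1:100, function(i) {
    pl <- simulate_viability_plate("drug", c(drug = 0.5), seed = 100 + i)
    rv <- relative_viability(pl)
    rv$summary$p_vs_control[rv$summary$treatment == "drug"]
  }, numeric(1))
  expect_gt(mean(ps < 0.001), 0.9)
})
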