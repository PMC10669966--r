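#' Specification for a synthetic subtype count matrix
#'
#' Defaults mirror the study design the pipeline targets: three liposarcoma
#' subtypes with 53 dedifferentiated (DDLPS), 54 myxoid (MLPS) and 24
#' pleomorphic (PLPS) samples, negative-binomial counts with dispersion
#' 0.1, gene baseline log2 means uniform on (0, 6) at a depth of 1e6, and
#' library sizes log-uniform between 5e5 and 2e6.
#'
#' @param n_genes number of genes.
#' @param group_sizes named integer vector, subtype -> sample count (each
#'   >= 2).
#' @param baseline_log_mean_range range of per-gene baseline log2 mean
#'   expression (at library size 1e6).
#' @param dispersion NB dispersion phi; variance = mu + phi * mu^2.
#' @param planted_degs data frame with columns `gene`, `subtype`, `effect`
#'   (log2 effect size >= 0; rows with effect 0 are inert). NULL for none.
#' @param library_size_range range of library sizes (drawn log-uniformly).
#' @param seed RNG seed.
#' @return A validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 2000,
                            group_sizes = c(DDLPS = 53, MLPS = 54, PLPS = 24),
                            baseline_log_mean_range = c(0, 6),
                            dispersion = 0.1,
                            planted_degs = NULL,
                            library_size_range = c(5e5, 2e6),
                            seed = 1L) {
  if (n_genes < 1) stop("n_genes must be positive")
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    stop("group_sizes must be named by subtype")
  }
  if (any(group_sizes < 2)) {
    stop("every subtype needs >= 2 samples (dispersion estimation)")
  }
  if (dispersion <= 0) stop("dispersion must be positive")
  if (length(baseline_log_mean_range) != 2 ||
      diff(baseline_log_mean_range) < 0) {
    stop("baseline_log_mean_range must be an increasing pair")
  }
  if (any(library_size_range <= 0) || diff(library_size_range) < 0) {
    stop("library_size_range must be a positive increasing pair")
  }
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  if (!is.null(planted_degs)) {
    stopifnot(all(c("gene", "subtype", "effect") %in% names(planted_degs)))
    if (!all(planted_degs$gene %in% genes)) stop("planted gene id outside universe")
    if (!all(planted_degs$subtype %in% names(group_sizes))) {
      stop("planted subtype not in group_sizes")
    }
    if (any(planted_degs$effect < 0)) stop("planted effect sizes must be >= 0")
    if (anyDuplicated(planted_degs[, c("gene", "subtype")])) {
      stop("planted gene ids must be unique per subtype")
    }
  }
  structure(list(
    n_genes = n_genes, genes = genes, group_sizes = group_sizes,
    baseline_log_mean_range = baseline_log_mean_range,
    dispersion = dispersion, planted_degs = planted_degs,
    library_size_range = library_size_range, seed = as.integer(seed)
  ), class = "simulation_spec")
}

#' Simulate a subtype count matrix with planted subtype-specific genes
#'
#' Counts are NB(mu, phi) with `mu = 2^baseline * library_size / 1e6`;
#' planted genes have their mean multiplied by `2^effect` in their subtype
#' only. Identical specs (including seed) give identical matrices.
#'
#' @param spec a [simulation_spec()].
#' @return List with `counts` (a [count_matrix()]) and `truth`, the ground
#'   truth table of effectively planted DEGs (columns `gene`, `subtype`,
#'   `effect`; rows with effect 0 omitted).
#' @export
simulate_subtype_counts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    subtypes <- rep(names(spec$group_sizes), spec$group_sizes)
    n <- length(subtypes)
    sample_ids <- paste0(subtypes, "_", unlist(lapply(spec$group_sizes, seq_len)))
    baselog <- stats::runif(spec$n_genes, spec$baseline_log_mean_range[1],
                            spec$baseline_log_mean_range[2])
    lib <- exp(stats::runif(n, log(spec$library_size_range[1]),
                            log(spec$library_size_range[2])))
    mu <- outer(2^baselog, lib / 1e6)
    if (!is.null(spec$planted_degs)) {
      for (i in seq_len(nrow(spec$planted_degs))) {
        pd <- spec$planted_degs[i, ]
        if (pd$effect > 0) {
          gi <- match(pd$gene, spec$genes)
          mu[gi, subtypes == pd$subtype] <-
            mu[gi, subtypes == pd$subtype] * 2^pd$effect
        }
      }
    }
    cts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
                  nrow = spec$n_genes,
                  dimnames = list(spec$genes, sample_ids))
    truth <- spec$planted_degs
    if (is.null(truth)) {
      truth <- data.frame(gene = character(), subtype = character(),
                          effect = numeric(), stringsAsFactors = FALSE)
    } else {
      truth <- truth[truth$effect > 0, , drop = FALSE]
      rownames(truth) <- NULL
    }
    list(counts = count_matrix(cts, stats::setNames(subtypes, sample_ids)),
         truth = truth)
  })
}

#' Specification for a synthetic healthy/cancer expression compendium
#'
#' Emulates a multi-tissue expression reference: per-tissue sample groups,
#' housekeeping genes high in every tissue, tissue-specific genes high only
#' in their designated tissues, and tissue sample counts that straddle the
#' minimum-datapoint rule. Defaults use the reference layout of 95 healthy
#' and 106 cancerous tissue types.
#'
#' @param genes gene universe (character).
#' @param n_healthy_tissues,n_cancer_tissues tissue counts (defaults 95 and
#'   106).
#' @param samples_per_tissue single integer, or a range from which each
#'   tissue's sample count is drawn uniformly (default `c(3, 12)`, which
#'   straddles the default <6-datapoint filter).
#' @param housekeeping_genes gene ids high in all tissues.
#' @param tissue_specific_genes named list: gene id -> character vector of
#'   tissue labels where the gene is high (labels as generated:
#'   `healthy_01`..., `cancer_001`...).
#' @param background_mean,signal_mean log-scale expression of background
#'   and high genes (defaults 5 and 14).
#' @param noise_sd within-tissue sample noise (default 0.4).
#' @param seed RNG seed.
#' @return A validated list of class `compendium_spec`.
#' @export
compendium_spec <- function(genes = sprintf("gene_%05d", 1:1000),
                            n_healthy_tissues = 95,
                            n_cancer_tissues = 106,
                            samples_per_tissue = c(3, 12),
                            housekeeping_genes = character(),
                            tissue_specific_genes = list(),
                            background_mean = 5, signal_mean = 14,
                            noise_sd = 0.4, seed = 1L) {
  if (n_healthy_tissues < 1 || n_cancer_tissues < 1) {
    stop("tissue counts must be positive")
  }
  if (length(samples_per_tissue) == 1) {
    samples_per_tissue <- rep(samples_per_tissue, 2)
  }
  if (any(samples_per_tissue < 1)) stop("samples_per_tissue must be >= 1")
  tissues <- c(
    sprintf("healthy_%02d", seq_len(n_healthy_tissues)),
    sprintf("cancer_%03d", seq_len(n_cancer_tissues))
  )
  categories <- stats::setNames(
    rep(c("healthy", "cancer"), c(n_healthy_tissues, n_cancer_tissues)),
    tissues
  )
  if (!all(housekeeping_genes %in% genes)) {
    stop("housekeeping gene absent from gene universe")
  }
  if (length(tissue_specific_genes)) {
    if (!all(names(tissue_specific_genes) %in% genes)) {
      stop("tissue-specific gene absent from gene universe")
    }
    bad <- setdiff(unlist(tissue_specific_genes), tissues)
    if (length(bad)) {
      stop("unknown tissue label(s) in tissue_specific_genes: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(
    genes = genes, tissues = tissues, categories = categories,
    samples_per_tissue = samples_per_tissue,
    housekeeping_genes = housekeeping_genes,
    tissue_specific_genes = tissue_specific_genes,
    background_mean = background_mean, signal_mean = signal_mean,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "compendium_spec")
}

#' Simulate a healthy/cancer expression compendium
#'
#' Values are continuous log-scale expression scores. Housekeeping genes
#' sit at `signal_mean` in every tissue; each tissue-specific gene sits at
#' `signal_mean` only in its designated tissues; all other values are
#' background. The separation between signal and background is chosen so
#' that top-k membership is guaranteed by construction for any `k` at least
#' the number of high genes in the tissue.
#'
#' @param spec a [compendium_spec()].
#' @return Data frame with columns `sample_id`, `tissue`, `category`, then
#'   one numeric column per gene.
#' @export
simulate_compendium <- function(spec) {
  stopifnot(inherits(spec, "compendium_spec"))
  with_seed(spec$seed, {
    n_per <- if (spec$samples_per_tissue[1] == spec$samples_per_tissue[2]) {
      rep(spec$samples_per_tissue[1], length(spec$tissues))
    } else {
      sample(spec$samples_per_tissue[1]:spec$samples_per_tissue[2],
             length(spec$tissues), replace = TRUE)
    }
    gene_base <- stats::rnorm(length(spec$genes), spec$background_mean, 1)
    names(gene_base) <- spec$genes
    rows <- vector("list", length(spec$tissues))
    for (ti in seq_along(spec$tissues)) {
      tis <- spec$tissues[ti]
      n <- n_per[ti]
      means <- gene_base
      means[spec$housekeeping_genes] <- spec$signal_mean
      for (g in names(spec$tissue_specific_genes)) {
        if (tis %in% spec$tissue_specific_genes[[g]]) {
          means[g] <- spec$signal_mean
        }
      }
      vals <- matrix(stats::rnorm(n * length(means), mean = rep(means, each = n),
                                  sd = spec$noise_sd),
                     nrow = n, dimnames = list(NULL, spec$genes))
      rows[[ti]] <- data.frame(
        sample_id = paste0(tis, "_s", seq_len(n)),
        tissue = tis,
        category = unname(spec$categories[tis]),
        vals,
        check.names = FALSE, stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  })
}

#' Simulate an immunohistochemistry scoring table
#'
#' Each sample draws a subtype from `subtype_mix` and an H-score from that
#' subtype's truncated-normal distribution on [0, 300]; staining intensity
#' and percent positive cells are then back-derived so that
#' intensity x percent reproduces the H-score (intensity is the smallest
#' level in 1..3 keeping percent <= 100; H-score 0 gives intensity 0).
#' Sex and metastasis covariates are drawn independently of the H-score,
#' so any association with them is null by construction.
#'
#' @param n_samples number of samples.
#' @param subtype_mix named numeric vector of subtype proportions.
#' @param hscore_params named list: subtype -> `c(mean, sd)` of the H-score
#'   distribution (mean must lie in [0, 300]).
#' @param seed RNG seed.
#' @return Data frame with columns `sample_id`, `subtype`, `sex`,
#'   `metastasis`, `intensity`, `percent_positive`, `h_score`.
#' @export
simulate_ihc_table <- function(n_samples,
                               subtype_mix = c(DDLPS = 0.4, MLPS = 0.4,
                                               PLPS = 0.2),
                               hscore_params = list(DDLPS = c(60, 60),
                                                    MLPS = c(180, 70),
                                                    PLPS = c(50, 50)),
                               seed = 1L) {
  stopifnot(all(names(subtype_mix) %in% names(hscore_params)))
  for (p in hscore_params) {
    if (p[1] < 0 || p[1] > 300 || p[2] < 0) {
      stop("H-score distribution must have mean in [0, 300] and sd >= 0")
    }
  }
  with_seed(seed, {
    subtype <- sample(names(subtype_mix), n_samples, replace = TRUE,
                      prob = subtype_mix)
    h <- vapply(subtype, function(st) {
      pars <- hscore_params[[st]]
      min(max(stats::rnorm(1, pars[1], pars[2]), 0), 300)
    }, numeric(1))
    intensity <- ifelse(h == 0, 0L, pmax(1L, as.integer(ceiling(h / 100))))
    percent <- ifelse(intensity == 0, 0, h / pmax(intensity, 1))
    data.frame(
      sample_id = sprintf("ihc_%03d", seq_len(n_samples)),
      subtype = unname(subtype),
      sex = sample(c("male", "female"), n_samples, replace = TRUE),
      metastasis = sample(c("present", "absent"), n_samples, replace = TRUE,
                          prob = c(0.05, 0.95)),
      intensity = unname(intensity),
      percent_positive = unname(percent),
      h_score = unname(h),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate qPCR Ct triplicates for a relative-expression experiment
#'
#' Generates target and reference-gene Ct triplicates per sample plus a
#' calibrator row. For a sample with true relative expression R, the
#' noise-free target/reference Ct difference is the calibrator's difference
#' minus log2(R), so the downstream delta-delta-Ct readout recovers R
#' exactly when `ct_noise_sd = 0`.
#'
#' @param n_samples number of samples (ignored when
#'   `true_relative_expression` is named per sample).
#' @param true_relative_expression positive scalar or vector (recycled to
#'   `n_samples`) of true expression relative to the calibrator.
#' @param ct_noise_sd per-replicate Ct noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @param calibrator_delta_ct the calibrator's true Ct difference
#'   (default 2).
#' @return Data frame with one row per sample plus a calibrator row
#'   (`is_calibrator`), columns `target_ct_1..3`, `reference_ct_1..3`.
#' @export
simulate_qpcr <- function(n_samples, true_relative_expression = 1,
                          ct_noise_sd = 0, seed = 1L,
                          calibrator_delta_ct = 2) {
  if (ct_noise_sd < 0) stop("ct_noise_sd must be >= 0")
  if (any(true_relative_expression <= 0)) {
    stop("true relative expression must be positive")
  }
  rel <- rep_len(true_relative_expression, n_samples)
  with_seed(seed, {
    make_rows <- function(ids, dct) {
      ref_mean <- stats::runif(length(ids), 18, 24)
      ref <- matrix(stats::rnorm(3 * length(ids), rep(ref_mean, each = 3),
                                 ct_noise_sd), ncol = 3, byrow = TRUE)
      tgt <- matrix(stats::rnorm(3 * length(ids), rep(ref_mean + dct, each = 3),
                                 ct_noise_sd), ncol = 3, byrow = TRUE)
      colnames(ref) <- paste0("reference_ct_", 1:3)
      colnames(tgt) <- paste0("target_ct_", 1:3)
      data.frame(sample_id = ids, tgt, ref, stringsAsFactors = FALSE)
    }
    dct <- calibrator_delta_ct - log2(rel)
    out <- rbind(
      cbind(make_rows(sprintf("sample_%03d", seq_len(n_samples)), dct),
            is_calibrator = FALSE),
      cbind(make_rows("calibrator", calibrator_delta_ct),
            is_calibrator = TRUE)
    )
    attr(out, "true_relative_expression") <- rel
    out
  })
}

#' Simulate a 96-well luminescence viability plate
#'
#' Eight replicate wells per treatment plus eight control and eight
#' medium-background wells. Each well reads
#' `background + effect * signal + noise`; the control treatment has
#' effect 1, so after background subtraction its mean maps to 100%
#' relative viability downstream.
#'
#' @param treatments character vector of treatment labels (control and
#'   background added automatically).
#' @param true_effects named numeric vector in (0, Inf), treatment ->
#'   viability fraction relative to control.
#' @param signal_mean control luminescence above background.
#' @param background_mean medium background luminescence.
#' @param noise_sd per-well noise standard deviation.
#' @param n_wells wells per treatment (default 8).
#' @param seed RNG seed.
#' @return Data frame with columns `well`, `treatment`, `luminescence`;
#'   control wells labelled `"control"`, background wells `"background"`.
#' @export
simulate_viability_plate <- function(treatments, true_effects,
                                     signal_mean = 50000,
                                     background_mean = 2000,
                                     noise_sd = 1500, n_wells = 8,
                                     seed = 1L) {
  if (!all(treatments %in% names(true_effects))) {
    stop("every treatment needs a true effect")
  }
  if (any(true_effects <= 0)) stop("effects must be positive")
  labels <- c("background", "control", treatments)
  effects <- c(0, 1, unname(true_effects[treatments]))
  with_seed(seed, {
    rows <- lapply(seq_along(labels), function(i) {
      signal <- if (labels[i] == "background") 0 else effects[i] * signal_mean
      data.frame(
        well = paste0(labels[i], "_w", seq_len(n_wells)),
        treatment = labels[i],
        luminescence = background_mean + signal +
          stats::rnorm(n_wells, 0, noise_sd),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Write a compendium table as TSV
#'
#' @param compendium data frame from [simulate_compendium()].
#' @param path output file path.
#' @return Invisibly, `compendium`.
#' @export
write_compendium <- function(compendium, path) {
  utils::write.table(compendium, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(compendium)
}

#' Read a compendium table written by [write_compendium()]
#'
#' @param path input file path.
#' @return Data frame with `sample_id`, `tissue`, `category` and gene
#'   columns.
#' @export
read_compendium <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
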