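#' Pipeline configuration
#'
#' Collects every stage parameter with defaults equal to the analysis'
#' published operating point: sample QC deviation threshold 0.10, gene
#' filter min_count 10 / min_total_count 15, compendium datapoint minimum
#' 6, per-tissue top-500 lists, membership caps 1 (healthy) and 3
#' (cancer), DEG thresholds logFC > 1.5 and p < 0.05.
#'
#' @param counts_path,meta_path TSV paths for counts and sample metadata;
#'   both NULL to simulate counts instead.
#' @param compendium_path compendium TSV path; NULL to simulate one.
#' @param gmt_path optional GMT gene-set library for enrichment.
#' @param outdir output directory for stage artifacts.
#' @param qc_threshold sample median log-CPM relative deviation limit.
#' @param min_count,min_total_count gene expression filter parameters.
#' @param min_datapoints,top_k,max_healthy,max_cancer exclusion-list
#'   parameters.
#' @param logfc_min,p_max,prior_df,prior_count DEG-calling parameters.
#' @param simulation list of overrides for [simulation_spec()] /
#'   [compendium_spec()] fields used when simulating (`n_genes`,
#'   `dispersion`, `n_planted`, `effect`, `n_housekeeping`,
#'   `n_tissue_specific`).
#' @param seed integer seed driving every simulated input.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path = NULL, meta_path = NULL,
                            compendium_path = NULL, gmt_path = NULL,
                            outdir = tempfile("lpsdeg_run_"),
                            qc_threshold = 0.10, min_count = 10,
                            min_total_count = 15, min_datapoints = 6,
                            top_k = 500, max_healthy = 1, max_cancer = 3,
                            logfc_min = 1.5, p_max = 0.05, prior_df = 10,
                            prior_count = 2, simulation = list(),
                            seed = 1L) {
  cfg <- list(
    counts_path = counts_path, meta_path = meta_path,
    compendium_path = compendium_path, gmt_path = gmt_path,
    outdir = outdir, qc_threshold = qc_threshold, min_count = min_count,
    min_total_count = min_total_count, min_datapoints = min_datapoints,
    top_k = top_k, max_healthy = max_healthy, max_cancer = max_cancer,
    logfc_min = logfc_min, p_max = p_max, prior_df = prior_df,
    prior_count = prior_count, simulation = simulation,
    seed = as.integer(seed)
  )
  res <- validate_config(cfg)
  if (is.character(res)) stop(paste(res, collapse = "; "))
  res
}

#' Validate a raw pipeline configuration
#'
#' Accepts a plain list (e.g. parsed from YAML via
#' [read_pipeline_config()]) and reports every violated constraint, not
#' just the first.
#'
#' @param raw named list of configuration values; missing fields take
#'   defaults.
#' @return A `pipeline_config` when valid, otherwise a character vector
#'   with one message per violated constraint.
#' @export
validate_config <- function(raw) {
  defaults <- list(
    counts_path = NULL, meta_path = NULL, compendium_path = NULL,
    gmt_path = NULL, outdir = tempfile("lpsdeg_run_"), qc_threshold = 0.10,
    min_count = 10, min_total_count = 15, min_datapoints = 6, top_k = 500,
    max_healthy = 1, max_cancer = 3, logfc_min = 1.5, p_max = 0.05,
    prior_df = 10, prior_count = 2, simulation = list(), seed = 1L
  )
  unknown <- setdiff(names(raw), names(defaults))
  cfg <- utils::modifyList(defaults, raw[setdiff(names(raw), unknown)])
  for (nm in setdiff(names(defaults), names(cfg))) cfg[nm] <- list(NULL)
  cfg <- cfg[names(defaults)]
  errors <- character()
  if (length(unknown)) {
    errors <- c(errors, paste("unknown field(s):", paste(unknown, collapse = ", ")))
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(cfg$qc_threshold) && cfg$qc_threshold >= 0,
      "qc_threshold must be a non-negative number")
  chk(num1(cfg$min_count) && cfg$min_count >= 0, "min_count must be >= 0")
  chk(num1(cfg$min_total_count) && cfg$min_total_count >= 0,
      "min_total_count must be >= 0")
  chk(num1(cfg$min_datapoints) && cfg$min_datapoints >= 1,
      "min_datapoints must be >= 1")
  chk(num1(cfg$top_k) && cfg$top_k >= 1, "top_k must be a positive integer")
  chk(num1(cfg$max_healthy) && cfg$max_healthy >= 0, "max_healthy must be >= 0")
  chk(num1(cfg$max_cancer) && cfg$max_cancer >= 0, "max_cancer must be >= 0")
  chk(num1(cfg$logfc_min) && cfg$logfc_min >= 0, "logfc_min must be >= 0")
  chk(num1(cfg$p_max) && cfg$p_max >= 0 && cfg$p_max <= 1,
      "p_max must lie in [0, 1]")
  chk(num1(cfg$prior_df) && cfg$prior_df >= 0, "prior_df must be >= 0")
  chk(num1(cfg$prior_count) && cfg$prior_count >= 0, "prior_count must be >= 0")
  chk(num1(cfg$seed), "seed must be a number")
  if (!is.null(cfg$counts_path) && is.null(cfg$meta_path)) {
    errors <- c(errors, "counts_path given without meta_path")
  }
  if (length(errors)) return(errors)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#'
#' Round-trips with [read_pipeline_config()].
#'
#' @param config a `pipeline_config`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file written by [write_pipeline_config()] or by hand.
#' @return A validated `pipeline_config` (errors are raised).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation)) raw$simulation <- as.list(raw$simulation)
  res <- validate_config(raw)
  if (is.character(res)) stop(paste(res, collapse = "; "))
  res
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full discovery pipeline
#'
#' Ingest (or simulate) counts, apply sample and gene QC, build the
#' compendium exclusion list, call one-vs-rest DEGs per subtype, and (when
#' a GMT library is configured) run gene-set over-representation on each
#' DEG list. Every stage writes its artifact as TSV under
#' `config$outdir`, and a manifest (JSON) records parameters, seeds and
#' item counts per stage. Reruns with an identical config reproduce
#' identical outputs.
#'
#' @param config a `pipeline_config`.
#' @return The manifest, invisibly a list; also written to
#'   `outdir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  sim <- config$simulation
  simpar <- function(name, default) {
    if (!is.null(sim[[name]])) sim[[name]] else default
  }

  truth <- NULL
  cm <- .stage("ingest", {
    if (!is.null(config$counts_path)) {
      read_count_matrix(config$counts_path, config$meta_path)
    } else {
      n_genes <- simpar("n_genes", 2000)
      n_planted <- simpar("n_planted", 60)
      effect <- simpar("effect", 3)
      group_sizes <- unlist(simpar("group_sizes",
                                   c(DDLPS = 53, MLPS = 54, PLPS = 24)))
      genes <- sprintf("gene_%05d", seq_len(n_genes))
      planted <- if (n_planted > 0) {
        data.frame(
          gene = genes[seq_len(n_planted)],
          subtype = rep(names(group_sizes), length.out = n_planted),
          effect = effect, stringsAsFactors = FALSE
        )
      } else NULL
      spec <- simulation_spec(
        n_genes = n_genes, group_sizes = group_sizes,
        dispersion = simpar("dispersion", 0.1),
        planted_degs = planted, seed = config$seed
      )
      res <- simulate_subtype_counts(spec)
      truth <<- res$truth
      utils::write.table(res$truth, file.path(outdir, "ground_truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res$counts
    }
  })
  write_count_matrix(cm, file.path(outdir, "counts_raw.tsv"),
                     file.path(outdir, "samples.tsv"))

  qc <- .stage("sample_qc", {
    filter_samples_by_median_logcount(cm, threshold = config$qc_threshold)
  })
  write_qc_report(qc$report, file.path(outdir, "sample_qc.tsv"))
  kept <- qc$kept

  genes_kept <- .stage("gene_filter", {
    filter_genes_by_expression(kept, min_count = config$min_count,
                               min_total_count = config$min_total_count)
  })
  filtered <- kept[genes_kept, ]
  write_count_matrix(filtered, file.path(outdir, "counts_filtered.tsv"),
                     file.path(outdir, "samples_filtered.tsv"))

  exclusion <- .stage("exclusion_list", {
    compendium <- if (!is.null(config$compendium_path)) {
      read_compendium(config$compendium_path)
    } else {
      genes <- rownames(cm$counts)
      n_hk <- min(simpar("n_housekeeping", 20), length(genes))
      n_ts <- min(simpar("n_tissue_specific", 50), length(genes) - n_hk)
      cspec <- with_seed(config$seed + 1L, {
        hk <- sample(genes, n_hk)
        ts_genes <- sample(setdiff(genes, hk), n_ts)
        tissues <- c(sprintf("healthy_%02d", 1:95),
                     sprintf("cancer_%03d", 1:106))
        ts <- lapply(ts_genes, function(g) sample(tissues, sample(1:2, 1)))
        names(ts) <- ts_genes
        compendium_spec(genes = genes, housekeeping_genes = hk,
                        tissue_specific_genes = ts, seed = config$seed + 2L)
      })
      cmp <- simulate_compendium(cspec)
      write_compendium(cmp, file.path(outdir, "compendium.tsv"))
      cmp
    }
    exclusion_list_from_compendium(
      compendium, min_datapoints = config$min_datapoints, k = config$top_k,
      max_healthy = config$max_healthy, max_cancer = config$max_cancer
    )
  })
  write_exclusion_list(exclusion, file.path(outdir, "exclusion_list.tsv"))

  degs <- .stage("differential_expression", {
    call_subtype_degs(filtered, exclusion = exclusion,
                      logfc_min = config$logfc_min, p_max = config$p_max,
                      prior_df = config$prior_df,
                      prior_count = config$prior_count)
  })
  write_deg_tables(degs, outdir)

  enrichment <- NULL
  if (!is.null(config$gmt_path)) {
    enrichment <- .stage("enrichment", {
      lib <- read_gmt(config$gmt_path)
      res <- lapply(names(degs), function(st) {
        hits <- degs[[st]]$gene[degs[[st]]$is_deg]
        if (!length(hits)) return(NULL)
        er <- enrich(hits, lib, background = length(genes_kept))
        utils::write.table(er, file.path(outdir, paste0("enrichment_", st, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        er
      })
      stats::setNames(res, names(degs))
    })
  }

  manifest <- list(
    parameters = unclass(config)[c(
      "qc_threshold", "min_count", "min_total_count", "min_datapoints",
      "top_k", "max_healthy", "max_cancer", "logfc_min", "p_max",
      "prior_df", "prior_count", "seed"
    )],
    stages = list(
      ingest = list(n_genes = nrow(cm$counts), n_samples = ncol(cm$counts),
                    simulated = is.null(config$counts_path)),
      sample_qc = list(n_excluded = sum(qc$report$excluded),
                       n_kept = ncol(kept$counts)),
      gene_filter = list(n_kept = length(genes_kept)),
      exclusion_list = list(n_genes = length(exclusion$genes)),
      differential_expression = lapply(degs, function(d) sum(d$is_deg))
    ),
    outputs = list(outdir = outdir)
  )
  if (!is.null(truth)) manifest$stages$ingest$n_planted <- nrow(truth)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
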