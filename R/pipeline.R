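## End-to-end orchestration: fit -> annotate -> enrich (one topic at a time)
## -> score -> report, with every artifact written to the output directory
## and a manifest recording versions, seeds and parameters.

#' Run the full pipeline
#'
#' Executes topic-model fitting, open-region annotation, per-topic
#' heritability enrichment and cell scoring from a configuration list (or a
#' YAML file with the same fields). Inputs may be given as file paths
#' (`counts_matrix`/`counts_regions`/`counts_barcodes`, `sumstats`,
#' `genotypes` prefix) or as in-memory objects (`counts`, `sumstats`,
#' `genotypes`).
#'
#' Configuration fields (defaults in parentheses): `K` (required), `seed`
#' (1), `fdr` (0.05), `ld_window_bp` (1e6), `n_blocks` (200), `max_iter`
#' (500), `tol` (1e-8), `fraction_min` (0.005), `out_dir` (NULL: write
#' nothing).
#'
#' @param config List or path to a YAML file.
#' @return List of class `scads_pipeline` with elements `fit`,
#'   `topic_annotation`, `annotation`, `enrichment`, `cell_scores`, `qc`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  get_opt <- function(name, default = NULL) config[[name]] %||% default
  K <- get_opt("K")
  if (is.null(K)) stop_format("config must specify K")
  seed <- get_opt("seed", 1L)
  fdr <- get_opt("fdr", 0.05)
  window_bp <- get_opt("ld_window_bp", 1e6)
  n_blocks <- get_opt("n_blocks", 200L)
  out_dir <- get_opt("out_dir")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_format("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e))
    })
  }

  counts <- stage("read_counts", {
    if (!is.null(config$counts)) config$counts
    else read_counts(config$counts_matrix, config$counts_regions,
                     config$counts_barcodes)
  })
  sumstats <- stage("read_sumstats", {
    if (is.data.frame(config$sumstats)) config$sumstats
    else read_sumstats(config$sumstats)
  })
  genotypes <- stage("read_genotypes", {
    if (inherits(config$genotypes, "scads_genotypes")) config$genotypes
    else read_genotypes(config$genotypes)
  })

  fit <- stage("fit", fit_topics(counts, K = K, seed = seed,
                                 max_iter = get_opt("max_iter", 500L),
                                 tol = get_opt("tol", 1e-8)))
  topic_annot <- stage("annotate",
                       derive_topic_annotation(counts, fit, fdr = fdr))
  annotation <- stage("annotate",
                      build_variant_annotation(topic_annot, counts$regions,
                                               genotypes$variants))
  qc <- stage("annotate",
              annotation_qc(annotation, topic_annot$pseudobulk_depth,
                            fraction_min = get_opt("fraction_min", 0.005)))
  ldscores <- stage("enrich",
                    compute_ld_scores(genotypes, annotation,
                                      window_bp = window_bp))
  enrichment <- stage("enrich",
                      estimate_topic_enrichments(sumstats, ldscores,
                                                 annotation,
                                                 n_blocks = n_blocks,
                                                 fraction_min =
                                                   get_opt("fraction_min",
                                                           0.005)))
  cell_scores <- stage("score",
                       score_cells(fit, topic_annot, annotation, enrichment,
                                   fdr = fdr))

  manifest <- list(package = "scads",
                   version = as.character(utils::packageVersion("scads")),
                   seed = seed, K = K, fdr = fdr,
                   ld_window_bp = window_bp, n_blocks = n_blocks,
                   n_cells = nrow(counts$counts),
                   n_regions = ncol(counts$counts),
                   n_variants = nrow(genotypes$variants),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(as.data.frame(fit$L), file.path(out_dir, "L.tsv"),
                     progress = FALSE)
    readr::write_tsv(as.data.frame(fit$F), file.path(out_dir, "F.tsv"),
                     progress = FALSE)
    jsonlite::write_json(glance(fit), file.path(out_dir, "fit_meta.json"),
                         auto_unbox = TRUE, digits = NA)
    write_annotation(annotation$A, genotypes$variants,
                     file.path(out_dir, "topic_annotations.tsv"))
    readr::write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"),
                     progress = FALSE)
    write_cell_scores(cell_scores, file.path(out_dir, "cell_scores.tsv"))
    jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (any(qc$power_warning))
    warning(sprintf("topic(s) %s below the 10M pseudobulk-read guidance",
                    paste(qc$topic[qc$power_warning], collapse = ", ")))

  structure(list(fit = fit, topic_annotation = topic_annot,
                 annotation = annotation, enrichment = enrichment,
                 cell_scores = cell_scores, qc = qc, manifest = manifest),
            class = "scads_pipeline")
}

#' @export
print.scads_pipeline <- function(x, ...) {
  cat("scads pipeline result\n")
  print(glance(x$fit))
  print(x$qc)
  print(glance(x$cell_scores))
  invisible(x)
}
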