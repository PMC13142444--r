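## Simulation benchmark harness: builds one synthetic scATAC-seq system
## (genome layout, topic masks and profiles, counts, fitted model,
## annotations, genotype panel and LD scores) and evaluates cell-score
## recovery against the ground truth for any GWAS architecture on top of it.
## The scATAC-seq side does not depend on the trait, so several
## architectures can share one system.

#' Build a benchmark system: synthetic scATAC-seq data plus genotype panel
#'
#' Simulates the genome layout, per-topic open masks and rate profiles, a
#' cell-by-region count matrix, fits the topic model at the true K, derives
#' the open-region and variant annotations, simulates a block-LD genotype
#' panel on the same variant grid and computes annotation LD scores.
#'
#' @param seed Master seed; all components derive their seeds from it.
#' @param K Number of topics.
#' @param n_cells Number of cells.
#' @param n_blocks,variants_per_block,regions_per_block Genome layout (see
#'   [simulate_genome()]).
#' @param n_ind Genotype panel size.
#' @param cv Profile coefficient of variation.
#' @param p_open Per-topic open probability for the masks.
#' @param rho,block_size LD structure of the genotype panel; `rho` is
#'   recycled across blocks, heterogeneous by default so LD-score magnitudes
#'   span a realistic range.
#' @param max_iter,tol Topic-model fit control.
#' @param fdr Open-region call FDR.
#' @param window_bp LD window.
#' @return List with all components (`genome`, `masks`, `profiles`,
#'   `counts`, `scatac_truth`, `fit`, `topic_annotation`, `annotation`,
#'   `genotypes`, `ldscores`).
#' @export
build_benchmark_system <- function(seed = 1L, K = 5L, n_cells = 2000L,
                                   n_blocks = 200L,
                                   variants_per_block = 200L,
                                   regions_per_block = 100L,
                                   n_ind = 2000L, cv = 0.2, p_open = 0.4,
                                   rho = seq(0.5, 0.97, length.out = 20L),
                                   block_size = 200L,
                                   max_iter = 80L, tol = 1e-6,
                                   fdr = 0.05, window_bp = 1e6) {
  genome <- simulate_genome(n_blocks = n_blocks,
                            variants_per_block = variants_per_block,
                            regions_per_block = regions_per_block,
                            seed = seed)
  J <- nrow(genome$regions)
  ## openness clustered at the LD-block scale: regulatory domains
  masks <- simulate_open_masks(K, J, p_open = p_open,
                               cluster_size = regions_per_block,
                               seed = seed + 1L)
  profiles <- simulate_topic_profiles(K, J, masks, cv = cv,
                                      seed = seed + 2L)
  sim <- simulate_scatac(profiles, n_cells = n_cells, seed = seed + 3L,
                         regions = genome$regions)
  fit <- suppressWarnings(fit_topics(sim$counts, K = K, seed = seed + 4L,
                                     max_iter = max_iter, tol = tol,
                                     loglik_every = 10L))
  topic_annot <- derive_topic_annotation(sim$counts, fit, fdr = fdr)
  annotation <- build_variant_annotation(topic_annot, genome$regions,
                                         genome$variants)
  genotypes <- simulate_genotypes(n_ind, nrow(genome$variants),
                                  block_size = block_size, rho = rho,
                                  seed = seed + 5L,
                                  variants = genome$variants)
  ldscores <- compute_ld_scores(genotypes, annotation,
                                window_bp = window_bp)
  ## ground-truth annotation (from the true masks, not the fitted calls)
  true_annotation <- build_variant_annotation(masks, genome$regions,
                                              genome$variants)
  list(genome = genome, masks = masks, profiles = profiles,
       counts = sim$counts, scatac_truth = sim$truth, fit = fit,
       topic_annotation = topic_annot, annotation = annotation,
       true_annotation = true_annotation, genotypes = genotypes,
       ldscores = ldscores)
}

#' Benchmark cell-score recovery for one GWAS architecture
#'
#' Simulates a trait on the system's genotype panel with enriched causal
#' fractions in the open regions of `enriched_topics` (true masks), runs the
#' enrichment and scoring stages, evaluates the ground-truth per-cell
#' enrichment from the realised effect sizes, and reports the Spearman
#' correlation between estimated and true cell scores.
#'
#' @param system A [build_benchmark_system()] result.
#' @param pi_b Baseline causal fraction.
#' @param enriched_topics Indices of causal topics.
#' @param fold `pi_k = fold * pi_b` for the causal topics.
#' @param h2 Trait heritability.
#' @param seed Trait seed.
#' @param n_blocks Jackknife blocks.
#' @return List with `spearman`, `scores` (the cell-score table),
#'   `true_scores`, `enrichment`, `e_true`.
#' @export
benchmark_trait <- function(system, pi_b, enriched_topics, fold, h2 = 0.5,
                            seed = 1L, n_blocks = 200L) {
  K <- nrow(system$masks)
  pi_k <- rep(0, K)
  pi_k[enriched_topics] <- fold * pi_b
  gwas <- simulate_gwas(system$genotypes, system$true_annotation,
                        pi_b = pi_b, pi_k = pi_k, h2 = h2, seed = seed)
  enrichment <- estimate_topic_enrichments(gwas$sumstats, system$ldscores,
                                           system$annotation,
                                           n_blocks = n_blocks)
  scores <- score_cells(system$fit, system$topic_annotation,
                        system$annotation, enrichment)
  e_true <- true_topic_enrichment(gwas$truth, system$true_annotation)
  true_scores <- true_cell_enrichment(system$scatac_truth$L, system$masks,
                                      system$true_annotation$v, e_true)
  ok <- !is.na(scores$score) & !is.na(true_scores)
  rho <- cor(scores$score[ok], true_scores[ok], method = "spearman")
  list(spearman = rho, scores = scores, true_scores = true_scores,
       enrichment = enrichment, e_true = e_true, gwas_truth = gwas$truth)
}
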