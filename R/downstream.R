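## Post-scoring analytics: variant accessibility vs. cell-score correlation
## over quantile bins, variant classification by fine-mapping PIP and
## correlation sign, nearest-gene assignment, regulon Fisher enrichment, and
## export of fine-mapping prior annotations.

#' Correlate variant accessibility with cell scores across score bins
#'
#' Cells in `cell_subset` are split into `n_bins` quantile bins by score
#' (equal cell counts; ties broken by barcode order). Per variant, the bin
#' accessibility is the read count of regions overlapping the window
#' `[pos - window_bp/2, pos + window_bp/2)` summed over the bin's cells;
#' CPM is the bin accessibility over the bin's total library size times 1e6.
#' The Pearson correlation of CPM against the bin's mean score is reported
#' for variants with CPM >= `cpm_min` in at least `min_bins` bins.
#'
#' @param counts A [cell_region_matrix()].
#' @param cell_scores A [score_cells()] table (or any tibble with `barcode`
#'   and `score`).
#' @param variants Tibble with `id`, `chrom`, `pos`.
#' @param cell_subset Barcodes to use (default: all scored cells).
#' @param window_bp Window width centred on the variant (default 500).
#' @param n_bins Number of score bins (default 5).
#' @param cpm_min,min_bins Retention filter: CPM >= `cpm_min` in at least
#'   `min_bins` bins.
#' @param bin_summary `"mean"` (default) or `"median"` score per bin used in
#'   the correlation.
#' @return Tibble: `id`, `pearson_r`, `n_bins_passing`, `retained`, plus a
#'   list-column `cpm` with the per-bin CPM values.
#' @export
variant_score_correlation <- function(counts, cell_scores, variants,
                                      cell_subset = NULL, window_bp = 500,
                                      n_bins = 5L, cpm_min = 5,
                                      min_bins = 2L,
                                      bin_summary = c("mean", "median")) {
  stopifnot(inherits(counts, "scads_counts"))
  bin_summary <- match.arg(bin_summary)
  scores <- tibble(barcode = cell_scores$barcode, score = cell_scores$score)
  scores <- scores[!is.na(scores$score), ]
  if (!is.null(cell_subset))
    scores <- scores[scores$barcode %in% cell_subset, ]
  if (nrow(scores) < n_bins)
    stop_format("fewer scored cells (%d) than bins (%d)", nrow(scores),
                n_bins)
  ## quantile bins with equal cell counts; barcode order breaks ties
  ord <- order(scores$score, scores$barcode)
  scores <- scores[ord, ]
  scores$bin <- ceiling(seq_len(nrow(scores)) * n_bins / nrow(scores))

  ridx <- match(scores$barcode, counts$barcodes)
  X <- counts$counts[ridx, , drop = FALSE]
  bin_lib <- vapply(seq_len(n_bins),
                    function(b) sum(X[scores$bin == b, , drop = FALSE]),
                    numeric(1))
  bin_score <- vapply(seq_len(n_bins), function(b) {
    v <- scores$score[scores$bin == b]
    if (bin_summary == "mean") mean(v) else median(v)
  }, numeric(1))

  ## region counts per bin (n_bins x J), then window sums per variant
  Bmat <- sparseMatrix(i = scores$bin, j = seq_len(nrow(scores)), x = 1,
                       dims = c(n_bins, nrow(scores)))
  bin_region <- as.matrix(Bmat %*% X)

  half <- window_bp / 2
  ## 0-based window [pos - half, pos + half) is 1-based [pos - half + 1, pos + half]
  win <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(start = variants$pos - half + 1,
                                                 end = variants$pos + half))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(win, regions_to_granges(counts$regions)))
  res <- purrr::map_dfr(seq_len(nrow(variants)), function(vi) {
    regs <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == vi]
    acc <- if (length(regs)) rowSums(bin_region[, regs, drop = FALSE])
           else rep(0, n_bins)
    cpm <- ifelse(bin_lib > 0, acc / bin_lib * 1e6, NA_real_)
    passing <- sum(cpm >= cpm_min, na.rm = TRUE)
    retained <- passing >= min_bins
    ok <- !is.na(cpm)
    r <- if (retained && sum(ok) >= 2 && sd(cpm[ok]) > 0 &&
             sd(bin_score[ok]) > 0)
      cor(cpm[ok], bin_score[ok]) else NA_real_
    tibble(id = variants$id[vi], pearson_r = r, n_bins_passing = passing,
           retained = retained, cpm = list(cpm))
  })
  res
}

#' Classify fine-mapped variants by score correlation
#'
#' Variants with PIP above `pip_min` are grouped by the sign of their
#' accessibility/score correlation when `|r| > cor_min`, else `"none"`;
#' variants not retained by the CPM filter are `"none"`.
#'
#' @param pip Tibble with `id` and `pip` (posterior inclusion
#'   probabilities in \[0, 1\]).
#' @param correlations A [variant_score_correlation()] table.
#' @param pip_min PIP threshold (default 0.3).
#' @param cor_min Absolute-correlation threshold (default 0.2).
#' @return Tibble of PIP-passing variants: `id`, `pip`, `pearson_r`,
#'   `group` in \{"positive", "negative", "none"\}.
#' @export
classify_variants <- function(pip, correlations, pip_min = 0.3,
                              cor_min = 0.2) {
  stopifnot(all(pip$pip >= 0 & pip$pip <= 1))
  out <- dplyr::inner_join(pip[pip$pip > pip_min, c("id", "pip")],
                           correlations[, c("id", "pearson_r", "retained")],
                           by = "id")
  out$group <- dplyr::case_when(
    !out$retained | is.na(out$pearson_r) ~ "none",
    out$pearson_r > cor_min ~ "positive",
    out$pearson_r < -cor_min ~ "negative",
    TRUE ~ "none")
  out[, c("id", "pip", "pearson_r", "group")]
}

#' Nearest protein-coding gene(s) per variant
#'
#' Returns the gene(s) minimising genomic distance from the variant position
#' to the gene interval (distance 0 inside the gene); exact distance ties
#' return all tied genes. Variants on chromosomes without genes get no
#' assignment.
#'
#' @param variants Tibble with `id`, `chrom`, `pos`.
#' @param gene_table Tibble with `gene`, `chrom`, `start`, `end` (0-based
#'   half-open intervals).
#' @return Tibble with one row per (variant, nearest gene): `id`, `gene`,
#'   `distance`.
#' @export
nearest_gene <- function(variants, gene_table) {
  purrr::map_dfr(seq_len(nrow(variants)), function(vi) {
    chrom <- variants$chrom[vi]
    pos0 <- variants$pos[vi] - 1  # 0-based position
    g <- gene_table[gene_table$chrom == chrom, ]
    if (nrow(g) == 0L)
      return(tibble(id = character(0), gene = character(0),
                    distance = numeric(0)))
    d <- pmax(0, pmax(g$start - pos0, pos0 - (g$end - 1)))
    dmin <- min(d)
    tibble(id = variants$id[vi], gene = g$gene[d == dmin], distance = dmin)
  })
}

#' Regulon enrichment of a target-gene set
#'
#' For each regulon, builds the 2x2 table of target-set membership against
#' regulon membership over the background gene universe and applies a
#' one-sided Fisher's exact test (alternative "greater"); the conditional
#' MLE odds ratio is reported as the enrichment, with BH correction across
#' regulons.
#'
#' @param target_genes Character vector of target genes (a subset of the
#'   background).
#' @param regulons Named list of character vectors (TF -> target gene set),
#'   or a tibble with columns `tf` and `gene`.
#' @param background_genes Character vector: the gene universe.
#' @param sample_or Report the sample odds ratio instead of the conditional
#'   MLE.
#' @return Tibble: `tf`, `n_regulon`, `n_overlap`, `odds_ratio`, `p`,
#'   `fdr`, sorted by p.
#' @export
regulon_enrichment <- function(target_genes, regulons, background_genes,
                               sample_or = FALSE) {
  if (is.data.frame(regulons))
    regulons <- split(regulons$gene, regulons$tf)
  background_genes <- unique(background_genes)
  target_genes <- intersect(unique(target_genes), background_genes)
  res <- purrr::map_dfr(names(regulons), function(tf) {
    reg <- intersect(unique(regulons[[tf]]), background_genes)
    a <- length(intersect(target_genes, reg))
    b <- length(setdiff(target_genes, reg))
    c_ <- length(reg) - a
    d <- length(background_genes) - a - b - c_
    if (length(target_genes) == 0L) {
      return(tibble(tf = tf, n_regulon = length(reg), n_overlap = 0L,
                    odds_ratio = NA_real_, p = 1))
    }
    ft <- fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                      alternative = "greater")
    or <- if (sample_or) {
      (a * d) / max(b * c_, .Machine$double.eps)
    } else unname(ft$estimate)
    tibble(tf = tf, n_regulon = length(reg), n_overlap = a,
           odds_ratio = or, p = ft$p.value)
  })
  res$fdr <- p.adjust(res$p, method = "BH")
  dplyr::arrange(res, .data$p)
}

#' Export fine-mapping prior annotations
#'
#' Writes the variant annotation columns of topics whose heritability
#' enrichment p-value is below `p_max` as an annot-style TSV for consumption
#' by functional-prior fine-mapping tools.
#'
#' @param enrichment A [estimate_topic_enrichments()] table.
#' @param annotation The matching `scads_variant_annotation`.
#' @param path Output path.
#' @param p_max Enrichment p-value threshold (default 0.05).
#' @return Invisibly, the exported tibble (zero annotation columns, with a
#'   warning, when no topic is significant).
#' @export
export_finemapping_priors <- function(enrichment, annotation, path,
                                      p_max = 0.05) {
  stopifnot(inherits(annotation, "scads_variant_annotation"))
  sig <- which(enrichment$p < p_max)
  if (length(sig) == 0L)
    warning("no topic with enrichment p < ", p_max, "; exporting no columns")
  A <- annotation$A[, sig, drop = FALSE]
  write_annotation(A, annotation$variants, path)
}
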