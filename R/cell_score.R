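## Per-cell disease-relevance scores. The score for cell i is the expected
## heritability enrichment in the cell's open chromatin:
##
##   c_i = sum_k l_ik s_k e_k / sum_k l_ik s_k,
##
## a convex combination of the topic enrichments e_k with weights l_ik s_k,
## where s_k is the (variant-weighted) open size of topic k. Its variance is
## the quadratic form of the weights with the enrichment covariance.

#' Variant-weighted open sizes of topics
#'
#' `s_k = sum_j I_kj * v_j`, the number of annotated variants falling in
#' topic k's open regions. `weight_by_variants = FALSE` gives the unweighted
#' count of open regions `sum_j I_kj` instead.
#'
#' @param annotation A `scads_variant_annotation`, or a list/argument pair
#'   `I` (K x regions binary) and `v` (per-region variant counts).
#' @param I,v Used when `annotation` is not given.
#' @param weight_by_variants Weight open regions by their variant counts
#'   (default TRUE; required for consistency with the score's denominator).
#' @return Numeric vector of topic sizes.
#' @export
topic_sizes <- function(annotation = NULL, I = NULL, v = NULL,
                        weight_by_variants = TRUE) {
  if (!is.null(annotation) && inherits(annotation, "scads_topic_annotation")) {
    I <- annotation$I
  }
  if (is.null(I)) stop_format("supply either an annotation or I")
  I <- as.matrix(I)
  if (weight_by_variants) {
    if (is.null(v)) stop_format("variant counts v required when weighting")
    stopifnot(length(v) == ncol(I))
    as.numeric(I %*% v)
  } else {
    rowSums(I)
  }
}

#' Per-cell disease-relevance scores
#'
#' Computes `c_i = sum_k l_ik s_k e_k / sum_k l_ik s_k` over included
#' topics. Excluded topics (annotation below the genome-fraction threshold)
#' are removed from both sums. Cells with zero total weight, or with `NA`
#' loadings (zero sequencing depth), receive `NA`.
#'
#' @param L Cells x K loading matrix.
#' @param s Topic sizes from [topic_sizes()].
#' @param e Topic enrichments (typically shrunken posterior means).
#' @param excluded Logical vector of topics to drop (default none).
#' @return Numeric vector of per-cell scores.
#' @export
compute_cell_scores <- function(L, s, e, excluded = NULL) {
  L <- as.matrix(L)
  K <- ncol(L)
  stopifnot(length(s) == K, length(e) == K)
  if (is.null(excluded)) excluded <- rep(FALSE, K)
  inc <- which(!excluded)
  if (length(inc) == 0L) stop_format("all topics excluded")
  W <- L[, inc, drop = FALSE] * rep(s[inc], each = nrow(L))
  tot <- rowSums(W)
  score <- as.numeric(W %*% e[inc]) / tot
  score[!is.finite(tot) | tot == 0] <- NA_real_
  score
}

#' Analytic variance of the per-cell score
#'
#' `Var(c_i) = sum_k sum_m (l_ik s_k)(l_im s_m) Cov(e_k, e_m) / S_i^2` with
#' `S_i = sum_k l_ik s_k`; the full symmetric double sum over topic pairs.
#' `half_sum = TRUE` restores the literal half-sum in which off-diagonal
#' terms are counted once.
#'
#' @param L Cells x K loading matrix.
#' @param s Topic sizes.
#' @param cov_e K x K enrichment covariance from
#'   [enrichment_covariance()].
#' @param excluded Logical vector of topics to drop.
#' @param half_sum Count each off-diagonal pair once instead of twice.
#' @return Numeric vector of per-cell variances.
#' @export
cell_score_variance <- function(L, s, cov_e, excluded = NULL,
                                half_sum = FALSE) {
  L <- as.matrix(L)
  K <- ncol(L)
  stopifnot(length(s) == K, all(dim(cov_e) == K))
  if (is.null(excluded)) excluded <- rep(FALSE, K)
  inc <- which(!excluded)
  W <- L[, inc, drop = FALSE] * rep(s[inc], each = nrow(L))
  W <- W / rowSums(W)
  Cv <- as.matrix(cov_e)[inc, inc, drop = FALSE]
  if (half_sum) {
    Cv <- Cv - 0.5 * (Cv - diag(diag(Cv), nrow = length(inc)))
  }
  rowSums((W %*% Cv) * W)
}

#' Per-cell z-scores, p-values and FDR
#'
#' Tests enrichment above background: `z_i = (c_i - 1) / sqrt(Var_i)` with a
#' one-sided upper-tail normal p-value, then BH-FDR across all scored cells.
#'
#' @param scores Per-cell scores.
#' @param variances Matching analytic variances.
#' @param fdr Significance threshold recorded in the output (default 0.05).
#' @return Tibble with columns `score`, `variance`, `z`, `p`, `fdr`,
#'   `significant`.
#' @export
cell_score_tests <- function(scores, variances, fdr = 0.05) {
  stopifnot(length(scores) == length(variances))
  zero_var <- !is.na(variances) & variances == 0 & !is.na(scores) &
    scores != 1
  if (any(zero_var))
    warning(sprintf("%d cell(s) with zero variance and score != 1; p set to 0",
                    sum(zero_var)))
  z <- (scores - 1) / sqrt(variances)
  z[zero_var] <- Inf
  p <- pnorm(z, lower.tail = FALSE)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  sig <- !is.na(q) & q <= fdr
  tibble(score = scores, variance = variances, z = z, p = p, fdr = q,
         significant = sig)
}

#' Ground-truth per-cell enrichment from simulation truth
#'
#' Evaluates the score formula with the true open-chromatin calls and true
#' topic enrichments; the benchmark ground truth for simulation studies.
#'
#' @param L Cells x K loading matrix (true loadings).
#' @param I_true K x regions true open masks.
#' @param v Per-region variant counts.
#' @param e_true True topic enrichments.
#' @return Numeric vector of true per-cell enrichments.
#' @export
true_cell_enrichment <- function(L, I_true, v, e_true) {
  s <- topic_sizes(I = I_true, v = v)
  compute_cell_scores(L, s, e_true)
}

#' Score every cell of a fitted topic model
#'
#' Combines the fitted loadings, the variant annotation and the enrichment
#' table into the per-cell score table: score, analytic variance, z, one-
#' sided p and BH-FDR. Topics flagged `excluded` in the enrichment table are
#' removed from the score; the enrichment covariance attached to the table
#' drives the variance.
#'
#' @param fit A [fit_topics()] result.
#' @param annotation The `scads_variant_annotation` used for the enrichment.
#' @param enrichment A [estimate_topic_enrichments()] table.
#' @param topic_annotation The `scads_topic_annotation` with the open calls.
#' @param fdr Significance threshold.
#' @param weight_by_variants,half_sum See [topic_sizes()] and
#'   [cell_score_variance()].
#' @return Tibble of class `scads_cell_scores`: `barcode`, `score`,
#'   `variance`, `z`, `p`, `fdr`, `significant`, `n_topics_used`.
#' @export
score_cells <- function(fit, topic_annotation, annotation, enrichment,
                        fdr = 0.05, weight_by_variants = TRUE,
                        half_sum = FALSE) {
  stopifnot(inherits(fit, "scads_topic_fit"),
            inherits(topic_annotation, "scads_topic_annotation"),
            inherits(annotation, "scads_variant_annotation"),
            inherits(enrichment, "scads_enrichment"))
  s <- topic_sizes(I = topic_annotation$I, v = annotation$v,
                   weight_by_variants = weight_by_variants)
  excl <- enrichment$excluded | s == 0
  cov_e <- attr(enrichment, "cov")
  scores <- compute_cell_scores(fit$L, s, enrichment$e_post, excluded = excl)
  vars <- cell_score_variance(fit$L, s, cov_e, excluded = excl,
                              half_sum = half_sum)
  vars[is.na(scores)] <- NA_real_
  out <- cell_score_tests(scores, vars, fdr = fdr)
  out <- dplyr::bind_cols(tibble(barcode = fit$barcodes), out)
  out$n_topics_used <- sum(!excl)
  class(out) <- c("scads_cell_scores", class(out))
  out
}

#' @rdname score_cells
#' @param x A `scads_cell_scores` table.
#' @param ... Unused.
#' @method glance scads_cell_scores
#' @export
glance.scads_cell_scores <- function(x, ...) {
  tibble(n_cells = nrow(x),
         n_scored = sum(!is.na(x$score)),
         n_significant = sum(x$significant, na.rm = TRUE),
         mean_score = mean(x$score, na.rm = TRUE),
         n_topics_used = x$n_topics_used[1])
}
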