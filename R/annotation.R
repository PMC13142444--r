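## Per-topic open-chromatin calling. For each topic the pseudobulk counts are
## compared against a GC-dependent baseline rate; regions whose rate exceeds
## the baseline (one-sided test on the log2 fold change, BH-controlled) are
## called open, and the calls are projected to variant-level annotations.

#' Estimate a GC-dependent baseline rate for one topic
#'
#' Regions are binned by GC content (deciles); within each bin a
#' two-component Poisson mixture is fitted to the pseudobulk counts by EM and
#' the lower component's mean is taken as the bin's background count. Bin
#' backgrounds are smoothed by a moving average across adjacent GC bins and
#' normalised by the topic's total reads so the result is a rate comparable
#' with the topic distribution `f_kj`.
#'
#' @param pseudobulk_row Numeric vector of per-region pseudobulk counts for
#'   one topic.
#' @param gc Numeric vector of per-region GC fractions.
#' @param total_reads The topic's total reads (`sum_j sum_i l_ik x_ij`),
#'   used as the rate normaliser; must be > 0.
#' @param n_bins Number of GC bins (default 10, i.e. deciles).
#' @return Numeric vector of strictly positive baseline rates, one per
#'   region, with a `dispersion` attribute holding the per-region
#'   quasi-Poisson dispersion (variance/mean) of the background component.
#' @export
estimate_gc_baseline <- function(pseudobulk_row, gc, total_reads,
                                 n_bins = 10L) {
  y <- round(as.numeric(pseudobulk_row))
  stopifnot(length(gc) == length(y), is.finite(total_reads))
  if (total_reads <= 0) stop_format("total_reads must be > 0")
  breaks <- unique(quantile(gc, probs = seq(0, 1, length.out = n_bins + 1L),
                            na.rm = TRUE))
  if (length(breaks) < 3L) {
    if (length(unique(y)) < 3L)
      warning("degenerate counts with constant GC; returning flat baseline")
    bg <- poisson_mixture_background(y)
    out <- rep(pmax(bg["mu"], 0.5) / total_reads, length(y))
    attr(out, "dispersion") <- rep(unname(bg["phi"]), length(y))
    return(out)
  }
  bin <- cut(gc, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  bins <- sort(unique(bin))
  fits <- vapply(bins, function(b) poisson_mixture_background(y[bin == b]),
                 numeric(2))
  ## moving-average smoothing across adjacent GC bins (window 3, truncated)
  smooth3 <- function(v) vapply(seq_along(v), function(i) {
    w <- max(1L, i - 1L):min(length(v), i + 1L)
    mean(v[w])
  }, numeric(1))
  sm <- smooth3(fits["mu", ])
  phi <- smooth3(fits["phi", ])
  out <- pmax(sm[match(bin, bins)], 0.5) / total_reads
  attr(out, "dispersion") <- phi[match(bin, bins)]
  out
}

## Two-component Poisson mixture EM; returns the smaller component mean and
## the background quasi-dispersion (variance/mean of the lower component).
## Falls back to the plain mean when the fit degenerates.
poisson_mixture_background <- function(y, max_iter = 200L, tol = 1e-8) {
  y <- as.numeric(y)
  if (length(y) < 5L || length(unique(y)) < 3L)
    return(c(mu = max(mean(y), 0.5), phi = 1))
  mu1 <- max(quantile(y, 0.25), 0.5)
  mu2 <- max(quantile(y, 0.95), mu1 * 2 + 1)
  pi1 <- 0.75
  r1 <- rep(1, length(y))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    l1 <- dpois(y, mu1, log = TRUE) + log(pi1)
    l2 <- dpois(y, mu2, log = TRUE) + log(1 - pi1)
    m <- pmax(l1, l2)
    denom <- m + log(exp(l1 - m) + exp(l2 - m))
    r1 <- exp(l1 - denom)
    pi1 <- mean(r1)
    if (pi1 < 1e-6 || pi1 > 1 - 1e-6) break
    mu1 <- max(sum(r1 * y) / sum(r1), 1e-8)
    mu2 <- max(sum((1 - r1) * y) / sum(1 - r1), 1e-8)
    ll <- sum(denom)
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  if (mu1 <= mu2) { mu_bg <- mu1; r_bg <- r1 } else { mu_bg <- mu2; r_bg <- 1 - r1 }
  vr <- sum(r_bg * (y - mu_bg)^2) / max(sum(r_bg), 1e-12)
  c(mu = mu_bg, phi = max(1, vr / max(mu_bg, 1e-12)))
}

#' MAP log2 fold-change test against a baseline
#'
#' For each region the pseudobulk count `y` is modelled as
#' `y ~ Poisson(mu0 * 2^delta)` with `mu0` the expected count under the
#' baseline, and `delta` (the log2 fold change) given a weak Gaussian prior
#' `N(0, prior_sd^2)`. The MAP estimate is found by Newton iteration, its
#' standard error from the Laplace approximation, and a one-sided upper-tail
#' normal p-value tests for openness (`f > f0`). Zero counts give a finite,
#' prior-shrunken estimate.
#'
#' @param pseudobulk Vector or K x regions matrix of pseudobulk counts.
#' @param baseline Baseline of matching shape. Interpreted as rates when
#'   `total_reads` is supplied (expected count = rate x total reads), else as
#'   expected counts directly.
#' @param total_reads Optional per-topic total reads (scalar, or vector of
#'   length K for matrix input).
#' @param prior_sd Prior standard deviation on the log2 fold change.
#' @param dispersion Quasi-Poisson dispersion factor(s) (variance/mean of
#'   the background counts, >= 1) inflating the standard errors; default 1
#'   (pure Poisson noise).
#' @return List with elements `lfc`, `se`, `z`, `p`, each matching the input
#'   shape.
#' @export
lfc_map_test <- function(pseudobulk, baseline, total_reads = NULL,
                         prior_sd = 2, dispersion = 1) {
  if (is.matrix(pseudobulk)) {
    stopifnot(all(dim(pseudobulk) == dim(as.matrix(baseline))))
    mu0 <- as.matrix(baseline)
    if (!is.null(total_reads)) mu0 <- mu0 * total_reads
    res <- lfc_map_vec(as.numeric(pseudobulk), as.numeric(mu0), prior_sd,
                       as.numeric(dispersion))
    lapply(res, function(v) matrix(v, nrow(pseudobulk), ncol(pseudobulk),
                                   dimnames = dimnames(pseudobulk)))
  } else {
    mu0 <- as.numeric(baseline)
    if (!is.null(total_reads)) mu0 <- mu0 * total_reads
    lfc_map_vec(as.numeric(pseudobulk), mu0, prior_sd,
                as.numeric(dispersion))
  }
}

lfc_map_vec <- function(y, mu0, prior_sd, dispersion = 1) {
  if (any(mu0 <= 0)) stop_format("baseline must be strictly positive")
  stopifnot(all(dispersion >= 1))
  v <- prior_sd^2
  ln2 <- log(2)
  delta <- pmin(pmax(log2((y + 0.1) / mu0), -6 * prior_sd), 6 * prior_sd)
  for (it in 1:100) {
    lam <- mu0 * 2^delta
    g <- y * ln2 - lam * ln2 - delta / v
    h <- lam * ln2^2 + 1 / v
    step <- g / h
    step <- pmin(pmax(step, -2), 2)
    delta <- delta + step
    if (max(abs(step)) < 1e-10) break
  }
  ## quasi-likelihood SE: Poisson curvature inflated by the dispersion
  se <- 1 / sqrt(mu0 * 2^delta * ln2^2 / dispersion + 1 / v)
  z <- delta / se
  list(lfc = delta, se = se, z = z, p = pnorm(z, lower.tail = FALSE))
}

#' Call open regions by Benjamini-Hochberg control
#'
#' Applies the BH procedure within each topic (each row when `pvals` is a
#' matrix) and calls a region open when its adjusted p-value is below `fdr`.
#'
#' @param pvals Vector or K x regions matrix of one-sided p-values.
#' @param fdr Target false discovery rate (default 0.05).
#' @return Binary 0/1 object of the same shape.
#' @export
call_open_regions <- function(pvals, fdr = 0.05) {
  stopifnot(fdr > 0, fdr < 1)
  bh <- function(p) {
    if (length(p) == 0L) return(integer(0))
    as.integer(p.adjust(p, method = "BH") <= fdr)
  }
  if (is.matrix(pvals)) {
    out <- t(apply(pvals, 1L, bh))
    dimnames(out) <- dimnames(pvals)
    out
  } else bh(pvals)
}

#' Derive per-topic open-region annotations from a fitted topic model
#'
#' Orchestrates [pseudobulk_counts()], [estimate_gc_baseline()],
#' [lfc_map_test()] and [call_open_regions()] for every topic.
#'
#' @param counts A [cell_region_matrix()] object with GC content available in
#'   `counts$regions$gc`.
#' @param fit A [fit_topics()] result.
#' @param fdr FDR threshold for open-region calls.
#' @param prior_sd Prior SD for the log2 fold change.
#' @return Object of class `scads_topic_annotation` with elements `I`
#'   (K x regions binary open calls), `baseline`, `lfc`, `lfc_se`, `pvals`
#'   (all K x regions), and `pseudobulk_depth` (per-topic total assigned
#'   reads).
#' @export
derive_topic_annotation <- function(counts, fit, fdr = 0.05, prior_sd = 2) {
  stopifnot(inherits(counts, "scads_counts"))
  if (!"gc" %in% names(counts$regions))
    stop_format("regions need a gc column; see read_regions()/region_gc_from_fasta()")
  Y <- pseudobulk_counts(counts, fit)
  Tk <- topic_total_reads(counts, fit)
  f0 <- matrix(0, fit$K, ncol(Y))
  phi <- matrix(1, fit$K, ncol(Y))
  for (k in seq_len(fit$K)) {
    b <- estimate_gc_baseline(Y[k, ], counts$regions$gc, Tk[k])
    f0[k, ] <- b
    phi[k, ] <- attr(b, "dispersion") %||% 1
  }
  test <- lfc_map_test(Y, f0, total_reads = Tk, prior_sd = prior_sd,
                       dispersion = phi)
  I <- call_open_regions(test$p, fdr = fdr)
  dimnames(I) <- dimnames(Y)
  structure(list(I = I, baseline = f0, lfc = test$lfc, lfc_se = test$se,
                 pvals = test$p, pseudobulk_depth = rowSums(Y),
                 fdr = fdr),
            class = "scads_topic_annotation")
}

#' @export
print.scads_topic_annotation <- function(x, ...) {
  cat(sprintf("scads_topic_annotation: %d topics x %d regions; open fractions %s\n",
              nrow(x$I), ncol(x$I),
              paste(sprintf("%.2f", rowMeans(x$I)), collapse = ", ")))
  invisible(x)
}

#' Project open-region calls to variant-level annotations
#'
#' A variant at 1-based position `pos` belongs to topic `k`'s annotation iff
#' `pos - 1` lies in some open region `[start, end)` of topic `k`
#' (overlapping open calls are merged first). Per-region variant counts
#' `v_j` are computed on the original, unmerged region set.
#'
#' @param I K x regions binary open-call matrix (or a
#'   `scads_topic_annotation`).
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param variants Tibble with `id`, `chrom`, `pos` (1-based).
#' @return Object of class `scads_variant_annotation` with elements `A`
#'   (variants x K binary matrix), `v` (per-region variant counts) and
#'   `genome_fraction` (per-topic fraction of variants annotated).
#' @export
build_variant_annotation <- function(I, regions, variants) {
  if (inherits(I, "scads_topic_annotation")) I <- I$I
  I <- as.matrix(I)
  stopifnot(ncol(I) == nrow(regions))
  gr_regions <- regions_to_granges(regions)
  gr_variants <- variants_to_granges(variants)
  K <- nrow(I)
  P <- nrow(variants)
  A <- matrix(0L, P, K)
  colnames(A) <- rownames(I) %||% paste0("topic", seq_len(K))
  for (k in seq_len(K)) {
    open <- which(I[k, ] == 1L)
    if (length(open) == 0L) next
    merged <- GenomicRanges::reduce(gr_regions[open])
    hit <- suppressWarnings(IRanges::overlapsAny(gr_variants, merged))
    A[hit, k] <- 1L
  }
  v <- suppressWarnings(GenomicRanges::countOverlaps(gr_regions,
                                                     gr_variants))
  structure(list(A = A, v = as.integer(v),
                 genome_fraction = colMeans(A),
                 variants = as_tibble(variants)),
            class = "scads_variant_annotation")
}

#' @export
print.scads_variant_annotation <- function(x, ...) {
  cat(sprintf("scads_variant_annotation: %d variants x %d topics; genome fractions %s\n",
              nrow(x$A), ncol(x$A),
              paste(sprintf("%.3f", x$genome_fraction), collapse = ", ")))
  invisible(x)
}

#' QC report for topic annotations
#'
#' Flags topics whose pseudobulk depth falls below the recommended 10 million
#' reads (power warning) and topics whose annotation covers less than 0.5% of
#' variants (excluded from the cell score, where small annotations carry
#' unreliable standard errors).
#'
#' @param annotation A `scads_variant_annotation` (or genome-fraction
#'   vector).
#' @param pseudobulk_depth Per-topic total assigned reads.
#' @param depth_min Pseudobulk depth below which power is flagged (default
#'   1e7).
#' @param fraction_min Genome fraction below which a topic is excluded
#'   (default 0.005).
#' @return Tibble with one row per topic: `topic`, `pseudobulk_depth`,
#'   `genome_fraction`, `power_warning`, `excluded`.
#' @export
annotation_qc <- function(annotation, pseudobulk_depth, depth_min = 1e7,
                          fraction_min = 0.005) {
  gf <- if (inherits(annotation, "scads_variant_annotation"))
    annotation$genome_fraction else as.numeric(annotation)
  stopifnot(length(gf) == length(pseudobulk_depth))
  tibble(topic = names(gf) %||% paste0("topic", seq_along(gf)),
         pseudobulk_depth = as.numeric(pseudobulk_depth),
         genome_fraction = gf,
         power_warning = pseudobulk_depth < depth_min,
         excluded = gf < fraction_min)
}
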