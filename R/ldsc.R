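## Self-contained stratified LD-score regression: annotation LD scores from a
## genotype panel, per-topic heritability enrichment with block-jackknife
## standard errors, the enrichment covariance approximation, and an
## empirical-Bayes shrinkage of the enrichment estimates.

#' Compute annotation LD scores from a genotype panel
#'
#' For variant p and annotation A_k,
#' `l_{A_k,p} = sum_q A_k(q) * r2_adj(p, q)` over variants q within
#' `window_bp` of p on the same chromosome, where `r2_adj = r2 - (1 - r2) /
#' (n - 2)` is the standard bias-adjusted squared correlation (toggle with
#' `adjust`). Monomorphic variants have r2 = 0 against all variants,
#' including themselves. The all-variant (total) LD score is always computed
#' alongside.
#'
#' @param genotypes A [genotype_panel()] object (>= 2 individuals, >= 3 when
#'   `adjust = TRUE`).
#' @param annotations Variants x K binary matrix (or a
#'   `scads_variant_annotation`), rows in the panel's variant order.
#' @param window_bp LD window in base pairs (default 1 Mb).
#' @param adjust Apply the r2 bias adjustment (default TRUE).
#' @param chunk_size Number of variants processed per block of the banded
#'   correlation computation.
#' @return Object of class `scads_ldscores`: list with `lA` (variants x K),
#'   `l_total`, `variants`, `window_bp`, `adjusted`.
#' @export
compute_ld_scores <- function(genotypes, annotations, window_bp = 1e6,
                              adjust = TRUE, chunk_size = 200L) {
  stopifnot(inherits(genotypes, "scads_genotypes"))
  if (inherits(annotations, "scads_variant_annotation"))
    annotations <- annotations$A
  A <- as.matrix(annotations)
  X <- genotypes$X
  vars <- genotypes$variants
  n <- nrow(X); P <- ncol(X)
  stopifnot(nrow(A) == P)
  if (n < 2L) stop_format("need at least 2 individuals")
  if (adjust && n < 3L)
    stop_format("r2 bias adjustment needs at least 3 individuals")
  if (is.null(colnames(A))) colnames(A) <- paste0("topic", seq_len(ncol(A)))

  ## standardise to unit-norm centred columns so crossprod gives Pearson r;
  ## monomorphic variants become all-zero columns (r = 0 everywhere)
  Z <- scale(X, center = TRUE, scale = FALSE)
  ss <- sqrt(colSums(Z^2))
  mono <- ss == 0
  ss[mono] <- 1
  Z <- sweep(Z, 2L, ss, "/")
  Z[, mono] <- 0

  lA <- matrix(0, P, ncol(A), dimnames = list(NULL, colnames(A)))
  l_total <- numeric(P)
  for (chrom in unique(vars$chrom)) {
    idx <- which(vars$chrom == chrom)
    idx <- idx[order(vars$pos[idx])]
    pos <- vars$pos[idx]
    m <- length(idx)
    starts <- seq(1L, m, by = chunk_size)
    for (s in starts) {
      cc <- s:min(s + chunk_size - 1L, m)
      lo <- findInterval(pos[cc[1L]] - window_bp - 1L, pos) + 1L
      hi <- findInterval(pos[cc[length(cc)]] + window_bp, pos)
      w <- lo:hi
      R <- crossprod(Z[, idx[cc], drop = FALSE], Z[, idx[w], drop = FALSE])
      r2 <- R^2
      if (adjust) r2 <- r2 - (1 - r2) / (n - 2)
      ## zero out pairs outside the window and all monomorphic pairs
      mask <- abs(outer(pos[cc], pos[w], "-")) <= window_bp
      r2 <- r2 * mask
      if (any(mono[idx[cc]])) r2[mono[idx[cc]], ] <- 0
      if (any(mono[idx[w]])) r2[, mono[idx[w]]] <- 0
      lA[idx[cc], ] <- r2 %*% A[idx[w], , drop = FALSE]
      l_total[idx[cc]] <- rowSums(r2)
    }
  }
  structure(list(lA = lA, l_total = l_total, variants = vars,
                 window_bp = window_bp, adjusted = adjust),
            class = "scads_ldscores")
}

#' @export
print.scads_ldscores <- function(x, ...) {
  cat(sprintf("scads_ldscores: %d variants x %d annotations (window %g bp, %s)\n",
              length(x$l_total), ncol(x$lA), x$window_bp,
              if (x$adjusted) "bias-adjusted" else "unadjusted"))
  invisible(x)
}

#' Write LD scores as an l2.ldscore-style TSV
#'
#' @param ldscores A `scads_ldscores` object.
#' @param path Output path.
#' @return Invisibly, the written tibble.
#' @export
write_ld_scores <- function(ldscores, path) {
  out <- tibble(SNP = ldscores$variants$id,
                CHR = ldscores$variants$chrom,
                BP = ldscores$variants$pos,
                baseL2 = ldscores$l_total)
  out <- dplyr::bind_cols(out, as_tibble(ldscores$lA))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}

#' Stratified LD-score regression for one annotation
#'
#' Regresses the GWAS chi-square statistics on `[1, N * l_total,
#' N * l_annot]` (plus optional baseline LD-score columns) by weighted least
#' squares with the standard heteroskedasticity weights
#' `1 / max(l_total, 1)`. Per-variant heritability is reconstructed from the
#' coefficients and the annotation values; the enrichment is the per-variant
#' heritability inside the annotation over the genome-wide per-variant
#' heritability. The standard error of the enrichment and the enrichment
#' p-value (jackknife z-test of proportion-h2 minus proportion-of-variants)
#' come from a leave-one-block-out jackknife over `n_blocks` contiguous
#' variant blocks.
#'
#' @param Z GWAS z-scores, aligned with the LD-score vectors.
#' @param N GWAS sample size (scalar or per-variant).
#' @param l_annot LD scores with respect to the target annotation.
#' @param l_total Total (all-variant) LD scores.
#' @param annot Binary target annotation vector (defines M_k and the
#'   enrichment numerator).
#' @param baseline Optional variants x B matrix of baseline annotation
#'   values, with `baseline_l` its LD scores.
#' @param baseline_l Optional LD scores matching `baseline`.
#' @param n_blocks Number of jackknife blocks (default 200; reduced
#'   automatically when there are fewer than 2,000 variants).
#' @param intercept `"fixed"` (default) constrains the regression intercept
#'   to 1, appropriate when the summary statistics carry no confounding
#'   inflation (as in simulation); `"free"` estimates it, as S-LDSC does on
#'   real data, at a substantial cost in precision of the total-heritability
#'   denominator on small panels.
#' @return A one-row tibble: `tau0`, `tau`, `e_hat`, `se`, `p`, `prop_h2`,
#'   `M`, `M_k`, `n_blocks`.
#' @export
sldsc_fit <- function(Z, N, l_annot, l_total, annot, baseline = NULL,
                      baseline_l = NULL, n_blocks = 200L,
                      intercept = c("fixed", "free")) {
  intercept <- match.arg(intercept)
  P <- length(Z)
  stopifnot(length(l_annot) == P, length(l_total) == P, length(annot) == P)
  if (length(N) == 1L) N <- rep(N, P)
  M_k <- sum(annot)
  if (M_k == 0L) stop_format("annotation is empty (M_k = 0)")
  if (P < 2000L) n_blocks <- max(2L, min(n_blocks, floor(P / 10)))
  n_blocks <- min(n_blocks, P)

  ## annotation-value columns (per-variant h2 = A_cols %*% tau) and their LD
  ## scores; column 1 is the all-variant base annotation
  if (is.null(baseline)) {
    A_cols <- cbind(base = 1, annot = annot)
    L_cols <- cbind(base = l_total, annot = l_annot)
  } else {
    stopifnot(!is.null(baseline_l))
    A_cols <- cbind(base = 1, as.matrix(baseline), annot = annot)
    L_cols <- cbind(base = l_total, as.matrix(baseline_l), annot = l_annot)
  }

  chi2 <- Z^2
  if (intercept == "fixed") {
    D <- N * L_cols
    y <- chi2 - 1
  } else {
    D <- cbind(intercept = 1, N * L_cols)
    y <- chi2
  }
  ## LDSC weights: overcounting 1/max(l, 1) times the heteroskedasticity
  ## term from a first-pass estimate of the polygenic chi-square inflation
  wt <- 1 / pmax(l_total, 1)
  slope <- max(0, sum(wt * (chi2 - 1) * N * l_total) /
                  sum(wt * (N * l_total)^2))
  wt <- wt / (1 + slope * N * l_total)^2
  if (qr(D)$rank < ncol(D)) stop_format("rank-deficient regression design")

  Dw <- D * sqrt(wt)
  yw <- y * sqrt(wt)
  block <- ceiling(seq_len(P) / (P / n_blocks))
  block <- pmin(block, n_blocks)
  XtX <- crossprod(Dw)
  Xty <- crossprod(Dw, yw)
  XtX_b <- array(0, c(ncol(D), ncol(D), n_blocks))
  Xty_b <- matrix(0, ncol(D), n_blocks)
  for (b in seq_len(n_blocks)) {
    ii <- which(block == b)
    XtX_b[, , b] <- crossprod(Dw[ii, , drop = FALSE])
    Xty_b[, b] <- crossprod(Dw[ii, , drop = FALSE], yw[ii])
  }

  ## enrichment and prop_h2 from a coefficient vector
  colsums_A <- colSums(A_cols)
  colsums_A_in <- colSums(A_cols * annot)
  stat_from_tau <- function(tau) {
    h_tot <- sum(colsums_A * tau)
    h_in <- sum(colsums_A_in * tau)
    prop_h2 <- h_in / h_tot
    e <- (h_in / M_k) / (h_tot / P)
    c(e = e, prop_h2 = prop_h2)
  }

  tau_of <- function(beta) if (intercept == "fixed") beta else beta[-1L]
  beta_full <- drop(solve(XtX, Xty))
  tau_full <- tau_of(beta_full)
  st_full <- stat_from_tau(tau_full)

  theta_e <- numeric(n_blocks)
  theta_d <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    beta_b <- drop(solve(XtX - XtX_b[, , b], Xty - Xty_b[, b]))
    st <- stat_from_tau(beta_b)
    theta_e[b] <- st["e"]
    theta_d[b] <- st["prop_h2"] - M_k / P
  }
  jack_se <- function(theta) {
    sqrt((n_blocks - 1) / n_blocks * sum((theta - mean(theta))^2))
  }
  se_e <- jack_se(theta_e)
  se_d <- jack_se(theta_d)
  d_full <- st_full["prop_h2"] - M_k / P
  p_enr <- if (se_d > 0) 2 * pnorm(abs(d_full / se_d), lower.tail = FALSE)
           else as.numeric(d_full == 0)
  tibble(tau0 = tau_full[["base"]], tau = tau_full[["annot"]],
         e_hat = st_full[["e"]], se = se_e, p = p_enr,
         prop_h2 = st_full[["prop_h2"]], M = P, M_k = M_k,
         n_blocks = n_blocks)
}

#' Covariance of topic enrichments
#'
#' `Cov(e_k, e_m) = w_k * w_m * Cor(A_k, A_m)`, approximating the
#' correlation of the annotation LD scores by the Pearson correlation of the
#' binary annotations across variants. Constant annotations (all 0 or all 1)
#' get zero off-diagonal correlation, with a warning.
#'
#' @param w Per-topic enrichment standard errors.
#' @param A Variants x K binary annotation matrix (or a
#'   `scads_variant_annotation`).
#' @return K x K covariance matrix with diagonal `w^2`.
#' @export
enrichment_covariance <- function(w, A) {
  if (inherits(A, "scads_variant_annotation")) A <- A$A
  A <- as.matrix(A)
  stopifnot(ncol(A) == length(w))
  sds <- apply(A, 2L, sd)
  const <- sds == 0
  if (any(const))
    warning(sprintf("%d constant annotation(s); off-diagonal correlation set to 0",
                    sum(const)))
  C <- diag(1, ncol(A))
  ok <- which(!const)
  if (length(ok) > 1L) C[ok, ok] <- cor(A[, ok, drop = FALSE])
  Cov <- outer(w, w) * C
  dimnames(Cov) <- list(colnames(A), colnames(A))
  Cov
}

#' Empirical-Bayes shrinkage of enrichment estimates
#'
#' Models the effects `delta_k = e_hat_k - 1` as draws from a mixture of
#' uniform components over a geometric grid of half-widths `a_m`
#' (optionally plus a point mass at zero), with observation noise
#' `delta_hat_k ~ N(delta_k, w_k^2)`. The mixture weights are fitted by
#' maximum likelihood (EM) across topics; the returned values are
#' `1 + E[delta_k | delta_hat_k]`.
#'
#' `mixcompdist = "halfuniform"` (default) uses one-sided components
#' `U(-a_m, 0)` and `U(0, a_m)`, which can represent the asymmetric,
#' non-negative structure of heritability enrichments — overlapping
#' annotations push every topic's enrichment above 1, and a mixture forced
#' to be symmetric about zero cannot encode that common shift and instead
#' declares all topics null. `"uniform"` restores symmetric components
#' `U(-a_m, a_m)`. The point mass is off by default: with only a handful of
#' topics it tends to absorb the whole mixture and collapse every estimate
#' to exactly 1.
#'
#' @param e_hat Enrichment point estimates.
#' @param w Their standard errors (> 0).
#' @param grid_mult Geometric spacing of the half-width grid (default 2).
#' @param mixcompdist `"halfuniform"` (one-sided components, default) or
#'   `"uniform"` (symmetric).
#' @param pointmass Include a point-mass-at-zero component.
#' @param max_iter,tol EM control.
#' @return Numeric vector of posterior-mean enrichments.
#' @export
shrink_enrichments <- function(e_hat, w, grid_mult = 2,
                               mixcompdist = c("halfuniform", "uniform"),
                               pointmass = FALSE,
                               max_iter = 2000L, tol = 1e-12) {
  mixcompdist <- match.arg(mixcompdist)
  stopifnot(length(e_hat) == length(w), all(w > 0))
  d <- e_hat - 1
  K <- length(d)
  a_min <- min(w) / 10
  a_max <- max(max(abs(d)) + 3 * max(w), a_min * grid_mult)
  a_grid <- a_min * grid_mult^(0:ceiling(log(a_max / a_min, grid_mult)))
  comp <- if (mixcompdist == "uniform") {
    cbind(lo = -a_grid, hi = a_grid)
  } else {
    cbind(lo = c(-a_grid, rep(0, length(a_grid))),
          hi = c(rep(0, length(a_grid)), a_grid))
  }
  M <- nrow(comp) + as.integer(pointmass)

  ## likelihood matrix K x M and conditional (truncated-normal) posterior
  ## means per component
  lik <- matrix(0, K, M)
  pmean <- matrix(0, K, M)
  if (pointmass) lik[, 1L] <- dnorm(d, 0, w)
  off <- as.integer(pointmass)
  for (m in seq_len(nrow(comp))) {
    lo <- comp[m, "lo"]; hi <- comp[m, "hi"]
    alpha <- (lo - d) / w
    beta <- (hi - d) / w
    mass <- pnorm(beta) - pnorm(alpha)
    lik[, m + off] <- mass / (hi - lo)
    tm <- ifelse(mass > 1e-300,
                 d + w * (dnorm(alpha) - dnorm(beta)) / mass,
                 pmin(pmax(d, lo), hi))
    pmean[, m + off] <- tm
  }

  pi_m <- rep(1 / M, M)
  for (it in seq_len(max_iter)) {
    num <- lik * rep(pi_m, each = K)
    denom <- rowSums(num)
    denom[denom == 0] <- 1e-300
    resp <- num / denom
    pi_new <- colMeans(resp)
    if (max(abs(pi_new - pi_m)) < tol) { pi_m <- pi_new; break }
    pi_m <- pi_new
  }
  num <- lik * rep(pi_m, each = K)
  denom <- rowSums(num)
  denom[denom == 0] <- 1e-300
  post <- rowSums(num * pmean) / denom
  1 + post
}

#' Estimate per-topic heritability enrichments
#'
#' Runs [sldsc_fit()] once per topic annotation (one topic at a time, as in
#' stratified LD-score regression with a single focal annotation), applies
#' the 0.5% genome-fraction exclusion rule, and shrinks the retained
#' estimates with [shrink_enrichments()] (excluded topics carry a posterior
#' mean of 1 by convention).
#'
#' @param sumstats Tibble with columns `SNP`, `N`, `Z` (see
#'   [read_sumstats()]); aligned with the LD scores by variant id.
#' @param ldscores A [compute_ld_scores()] result.
#' @param annotation A `scads_variant_annotation` built on the same variant
#'   set.
#' @param baseline,baseline_l Optional baseline annotation matrix and its LD
#'   scores (rows in the LD-score variant order).
#' @param n_blocks Jackknife blocks.
#' @param fraction_min Genome-fraction exclusion threshold (default 0.005).
#' @return Tibble of class `scads_enrichment`: `topic`, `tau`, `e_hat`,
#'   `se`, `p`, `e_post`, `genome_fraction`, `excluded`; the enrichment
#'   covariance matrix is attached as attribute `"cov"`.
#' @export
estimate_topic_enrichments <- function(sumstats, ldscores, annotation,
                                       baseline = NULL, baseline_l = NULL,
                                       n_blocks = 200L,
                                       fraction_min = 0.005,
                                       intercept = c("fixed", "free")) {
  intercept <- match.arg(intercept)
  stopifnot(inherits(ldscores, "scads_ldscores"),
            inherits(annotation, "scads_variant_annotation"))
  idx <- match(ldscores$variants$id, sumstats$SNP)
  if (all(is.na(idx)))
    stop_format("no overlap between sumstats SNP ids and the LD-score panel")
  keep <- which(!is.na(idx))
  Z <- sumstats$Z[idx[keep]]
  N <- sumstats$N[idx[keep]]
  A <- annotation$A[keep, , drop = FALSE]
  lA <- ldscores$lA[keep, , drop = FALSE]
  lt <- ldscores$l_total[keep]
  bl <- if (!is.null(baseline)) as.matrix(baseline)[keep, , drop = FALSE]
  bll <- if (!is.null(baseline_l)) as.matrix(baseline_l)[keep, , drop = FALSE]

  Kt <- ncol(A)
  fits <- purrr::map_dfr(seq_len(Kt), function(k) {
    sldsc_fit(Z, N, lA[, k], lt, A[, k], baseline = bl, baseline_l = bll,
              n_blocks = n_blocks, intercept = intercept)
  })
  out <- tibble(topic = colnames(A),
                tau = fits$tau,
                e_hat = fits$e_hat,
                se = fits$se,
                p = fits$p,
                genome_fraction = annotation$genome_fraction,
                excluded = annotation$genome_fraction < fraction_min)
  out$e_post <- rep(1, Kt)
  inc <- which(!out$excluded & out$se > 0)
  if (length(inc))
    out$e_post[inc] <- shrink_enrichments(out$e_hat[inc], out$se[inc])
  attr(out, "cov") <- enrichment_covariance(out$se, A)
  class(out) <- c("scads_enrichment", class(out))
  out
}
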