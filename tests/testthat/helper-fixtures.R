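## Shared fixtures, built in code at test time.

## small deterministic count object: n cells x J regions
toy_counts <- function(n = 5, J = 8, seed = 42, lambda = 3) {
  withr::with_seed(seed, {
    X <- matrix(rpois(n * J, lambda), n, J)
  })
  starts <- (seq_len(J) - 1) * 1000
  regions <- tibble::tibble(chrom = "chr1", start = starts,
                            end = starts + 500,
                            gc = seq(0.3, 0.7, length.out = J))
  cell_region_matrix(X, regions, sprintf("bc%02d", seq_len(n)))
}

## tiny genotype panel with hand-set dosages
toy_panel <- function(X, chrom = "chr1", spacing = 1000) {
  P <- ncol(X)
  genotype_panel(X, tibble::tibble(id = paste0("rs", seq_len(P)),
                                   chrom = chrom,
                                   pos = seq_len(P) * spacing,
                                   a1 = "A", a2 = "G"))
}

## brute-force LD scores: double loop over all variant pairs
brute_ld_scores <- function(panel, A, window_bp = 1e6, adjust = TRUE) {
  X <- panel$X
  n <- nrow(X); P <- ncol(X)
  A <- as.matrix(A)
  lA <- matrix(0, P, ncol(A))
  lt <- numeric(P)
  for (p in seq_len(P)) {
    for (q in seq_len(P)) {
      if (panel$variants$chrom[p] != panel$variants$chrom[q]) next
      if (abs(panel$variants$pos[p] - panel$variants$pos[q]) > window_bp) next
      if (sd(X[, p]) == 0 || sd(X[, q]) == 0) next
      r2 <- cor(X[, p], X[, q])^2
      if (adjust) r2 <- r2 - (1 - r2) / (n - 2)
      lt[p] <- lt[p] + r2
      lA[p, ] <- lA[p, ] + r2 * A[q, ]
    }
  }
  list(lA = lA, l_total = lt)
}

## brute-force variant-in-open-region annotation over all pairs
brute_variant_annotation <- function(I, regions, variants) {
  K <- nrow(I); P <- nrow(variants)
  A <- matrix(0L, P, K)
  v <- integer(nrow(regions))
  for (p in seq_len(P)) {
    for (j in seq_len(nrow(regions))) {
      inside <- variants$chrom[p] == regions$chrom[j] &&
        (variants$pos[p] - 1) >= regions$start[j] &&
        (variants$pos[p] - 1) < regions$end[j]
      if (inside) {
        v[j] <- v[j] + 1L
        for (k in seq_len(K)) if (I[k, j] == 1L) A[p, k] <- 1L
      }
    }
  }
  list(A = A, v = v)
}

## brute-force Eq.-style score and variance for one cell
brute_cell_score <- function(l, s, e) {
  num <- 0; den <- 0
  for (k in seq_along(l)) {
    num <- num + l[k] * s[k] * e[k]
    den <- den + l[k] * s[k]
  }
  num / den
}

brute_cell_variance <- function(l, s, C) {
  S <- sum(l * s)
  v <- 0
  for (k in seq_along(l)) for (m in seq_along(l)) {
    v <- v + l[k] * s[k] * l[m] * s[m] * C[k, m]
  }
  v / S^2
}
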