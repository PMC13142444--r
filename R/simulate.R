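## Synthetic-data generators: a block-structured genome layout shared by the
## region and variant grids, Poisson-NMF scATAC-seq counts, block-LD
## genotype panels, annotation-stratified GWAS traits, a null-trait suite,
## and the Bernoulli pseudobulk accessibility simulator.

#' Synthetic genome layout shared by regions and variants
#'
#' Lays out `n_blocks` independent LD blocks on one chromosome, far enough
#' apart (default 2 Mb) that a 1 Mb LD window never spans blocks. Each block
#' carries `regions_per_block` regions of `region_length` bp on a
#' `2 * region_length` stride and `variants_per_block` variants. Only a
#' fraction of the variants fall inside regions (default 10%: one variant in
#' each of `in_region_per_block` regions spread evenly across the block);
#' the rest sit in the uncovered gaps between regions. This mirrors
#' real accessibility maps, where peaks cover a few percent of the genome
#' and most GWAS variants lie outside any peak. Per-region GC content is
#' drawn uniformly on \[0.3, 0.7\] (the simulator has no GC bias; the
#' baseline estimator must recover a flat background).
#'
#' @param n_blocks Number of LD blocks.
#' @param variants_per_block,regions_per_block Grid sizes per block.
#' @param in_region_per_block Number of regions per block that contain one
#'   variant (defaults to 10% of the variants).
#' @param block_gap Distance between block starts (bp).
#' @param region_length Region width (bp).
#' @param seed Seed for the GC draw.
#' @return List with `regions` (tibble: chrom, start, end, gc) and
#'   `variants` (tibble: id, chrom, pos, a1, a2, block).
#' @export
simulate_genome <- function(n_blocks = 200L, variants_per_block = 200L,
                            regions_per_block = 100L,
                            in_region_per_block =
                              max(1L, round(0.1 * variants_per_block)),
                            block_gap = 2e6, region_length = 1000L,
                            seed = 1L) {
  stopifnot(in_region_per_block <= regions_per_block,
            in_region_per_block <= variants_per_block)
  R <- regions_per_block
  stride <- 2L * region_length
  offsets <- (seq_len(n_blocks) - 1L) * block_gap

  ## regions tile [0, R * stride) per block, covering every even interval
  region_start <- (seq_len(R) - 1L) * stride
  rs <- as.vector(outer(region_start, offsets, "+"))
  regions <- tibble(chrom = "chr1", start = rs, end = rs + region_length)
  regions$gc <- with_seed(seed, runif(nrow(regions), 0.3, 0.7))

  ## in-region variants: centre of evenly spaced regions (1-based pos)
  host <- floor((seq_len(in_region_per_block) - 1L) *
                  R / in_region_per_block) * stride
  pos_in <- host + region_length %/% 2L + 1L
  ## out-region variants: two slots per uncovered gap, filled evenly
  n_out <- variants_per_block - in_region_per_block
  gap_slots <- as.vector(rbind(region_start + region_length +
                                 region_length %/% 4L,
                               region_start + region_length +
                                 3L * (region_length %/% 4L)))
  stopifnot(n_out <= length(gap_slots))
  take <- round(seq(1L, length(gap_slots), length.out = n_out))
  pos_out <- gap_slots[take] + 1L
  pos_block <- sort(c(pos_in, pos_out))
  vp <- as.vector(outer(pos_block, offsets, "+"))
  variants <- tibble(id = sprintf("rs%d", seq_along(vp)),
                     chrom = "chr1", pos = vp, a1 = "A", a2 = "G",
                     block = rep(seq_len(n_blocks),
                                 each = variants_per_block))
  list(regions = regions, variants = variants)
}

#' Simulate per-topic open/closed masks
#'
#' Openness is drawn per topic at the level of contiguous clusters of
#' `cluster_size` regions (regulatory domains): all regions of a cluster
#' share one Bernoulli(`p_open`) draw. `cluster_size = 1` gives independent
#' regions. Clusters open in no topic are assigned one topic at random, so
#' every region in the peak set is a peak in at least one topic. Clustered
#' openness mirrors real cell-type annotations, whose peaks aggregate in
#' domains rather than scattering uniformly across the genome.
#'
#' @param K Number of topics.
#' @param J Number of regions.
#' @param p_open Per-topic open probability.
#' @param cluster_size Regions per openness cluster (default 1).
#' @param seed Seed.
#' @return K x J binary matrix.
#' @export
simulate_open_masks <- function(K, J, p_open = 0.4, cluster_size = 1L,
                                seed = 1L) {
  n_clust <- ceiling(J / cluster_size)
  with_seed(seed, {
    Ic <- matrix(as.integer(runif(K * n_clust) < p_open), K, n_clust)
    empty <- which(colSums(Ic) == 0L)
    if (length(empty))
      Ic[cbind(sample.int(K, length(empty), replace = TRUE), empty)] <- 1L
    I <- Ic[, rep(seq_len(n_clust), each = cluster_size), drop = FALSE]
    I <- I[, seq_len(J), drop = FALSE]
    rownames(I) <- paste0("topic", seq_len(K))
    I
  })
}

#' Simulate per-topic Poisson rate profiles
#'
#' For a closed region the log rate is drawn from `N(f0, sigma0^2)`, for an
#' open region from `N(f1, sigma1^2)`, with `exp(f1) / exp(f0)` equal to
#' `ratio` (default 7.25, the open/closed read-depth ratio) and the sigmas
#' set so the within-class coefficient of variation equals `cv`. The closed
#' anchor `f0` is chosen per topic so the expected rates sum to 1 across
#' regions, making a pure-topic cell's total rate approximately 1 before
#' depth scaling.
#'
#' @param K,J Topics and regions (must match `open_masks`).
#' @param open_masks K x J binary open masks.
#' @param cv Within-class coefficient of variation of the rates (>= 0).
#' @param ratio Open/closed rate ratio.
#' @param seed Seed.
#' @return K x J matrix of Poisson rates with the masks, cv and ratio
#'   recorded as attributes.
#' @export
simulate_topic_profiles <- function(K, J, open_masks, cv = 0,
                                    ratio = 7.25, seed = 1L) {
  stopifnot(all(dim(open_masks) == c(K, J)))
  if (cv < 0) stop_format("cv must be >= 0")
  sigma2 <- log(1 + cv^2)
  with_seed(seed, {
    Fp <- matrix(0, K, J)
    for (k in seq_len(K)) {
      n_open <- sum(open_masks[k, ])
      mean0 <- 1 / ((J - n_open) + ratio * n_open)  # E[rate | closed]
      mu0 <- log(mean0) - sigma2 / 2
      mu1 <- mu0 + log(ratio)
      mu <- ifelse(open_masks[k, ] == 1L, mu1, mu0)
      Fp[k, ] <- if (cv == 0) exp(mu)
                 else exp(rnorm(J, mu, sqrt(sigma2)))
    }
    rownames(Fp) <- rownames(open_masks)
    attr(Fp, "open_masks") <- open_masks
    attr(Fp, "cv") <- cv
    attr(Fp, "ratio") <- ratio
    Fp
  })
}

#' Simulate a scATAC-seq count matrix from topic profiles
#'
#' Cells get Dirichlet(`alpha`, ..., `alpha`) mixture weights over the K
#' topics and log-normal depths (median `depth_median`, sdlog
#' `depth_sdlog`); counts are Poisson with rate
#' `s_i * sum_k l'_ik f'_kj`.
#'
#' @param profiles K x J rate matrix from [simulate_topic_profiles()].
#' @param n_cells Number of cells.
#' @param alpha Dirichlet concentration (default `1/K`).
#' @param depth_median Median cell depth on the natural scale.
#' @param depth_sdlog SD of log depth.
#' @param seed Seed.
#' @param regions Optional region tibble (J rows, with `gc`); a uniform
#'   tiling with random GC is generated otherwise.
#' @return List with `counts` (a [cell_region_matrix()]) and `truth`
#'   (class `scads_scatac_truth`: `Lp` true weights, `Fp` rates, `L`/`F`
#'   multinomial parameterisation, `open_masks`, `depths`, `params`).
#' @export
simulate_scatac <- function(profiles, n_cells, alpha = NULL,
                            depth_median = 20000, depth_sdlog = 0.173,
                            seed = 1L, regions = NULL) {
  K <- nrow(profiles); J <- ncol(profiles)
  if (is.null(alpha)) alpha <- 1 / K
  if (is.null(regions)) {
    starts <- (seq_len(J) - 1L) * 1000
    regions <- tibble(chrom = "chrSIM", start = starts, end = starts + 1000,
                      gc = with_seed(seed + 1L, runif(J, 0.3, 0.7)))
  }
  stopifnot(nrow(regions) == J)
  with_seed(seed, {
    G <- matrix(rgamma(n_cells * K, shape = alpha, rate = 1), n_cells, K)
    Lp <- row_normalize(G)
    depths <- exp(rnorm(n_cells, log(depth_median), depth_sdlog))
    Lam <- (Lp * depths) %*% profiles
    x <- rpois(length(Lam), as.vector(Lam))
    X <- Matrix(matrix(x, n_cells, J), sparse = TRUE)
  })
  barcodes <- sprintf("cell_%d", seq_len(n_cells))
  counts <- cell_region_matrix(X, regions, barcodes)
  mult <- poisson_to_multinomial(list(Lp = Lp, Fp = profiles))
  truth <- structure(list(Lp = Lp, Fp = profiles, L = mult$L, F = mult$F,
                          open_masks = attr(profiles, "open_masks"),
                          depths = depths,
                          params = list(K = K, J = J, n_cells = n_cells,
                                        alpha = alpha,
                                        depth_median = depth_median,
                                        depth_sdlog = depth_sdlog,
                                        cv = attr(profiles, "cv"),
                                        ratio = attr(profiles, "ratio"),
                                        seed = seed)),
                     class = "scads_scatac_truth")
  list(counts = counts, truth = truth)
}

#' Simulate a block-LD genotype panel
#'
#' Within each block of `block_size` variants, two latent Gaussian
#' haplotypes per individual follow an AR(1) correlation `rho^|p-q|`;
#' haplotype alleles are formed by thresholding at the variant's allele
#' frequency (drawn uniformly from `maf_range`) and summed into dosages in
#' \{0, 1, 2\}. Blocks are independent.
#'
#' @param n_ind Number of individuals.
#' @param n_variants Number of variants.
#' @param block_size Variants per LD block.
#' @param rho AR(1) latent correlation, `0 <= rho < 1`; a scalar, or a
#'   vector recycled across blocks for heterogeneous LD strength (real
#'   genomes span a wide range of LD-score magnitudes).
#' @param maf_range Allele-frequency range, a subset of (0, 0.5\].
#' @param seed Seed.
#' @param variants Optional variant tibble (`id`, `chrom`, `pos`), e.g. from
#'   [simulate_genome()]; generated on a 1 kb grid otherwise.
#' @return A [genotype_panel()] with allele frequencies in
#'   `variants$maf`.
#' @export
simulate_genotypes <- function(n_ind, n_variants, block_size = 200L,
                               rho = 0.9, maf_range = c(0.05, 0.5),
                               seed = 1L, variants = NULL) {
  stopifnot(all(rho >= 0), all(rho < 1), min(maf_range) > 0,
            max(maf_range) <= 0.5)
  if (is.null(variants)) {
    nb <- ceiling(n_variants / block_size)
    off <- rep((seq_len(nb) - 1L) * 2e6, each = block_size)[seq_len(n_variants)]
    within <- rep((seq_len(block_size) - 1L) * 1000L,
                  nb)[seq_len(n_variants)]
    variants <- tibble(id = sprintf("rs%d", seq_len(n_variants)),
                       chrom = "chr1", pos = off + within + 1L,
                       a1 = "A", a2 = "G")
  }
  stopifnot(nrow(variants) == n_variants)
  n_blocks <- ceiling(n_variants / block_size)
  rho_b <- rep(rho, length.out = n_blocks)
  with_seed(seed, {
    maf <- runif(n_variants, maf_range[1], maf_range[2])
    X <- matrix(0L, n_ind, n_variants)
    thr <- qnorm(maf)
    for (b in seq_len(n_blocks)) {
      b0 <- (b - 1L) * block_size + 1L
      cols <- b0:min(b0 + block_size - 1L, n_variants)
      rho_k <- rho_b[b]
      ar_scale <- sqrt(1 - rho_k^2)
      E <- matrix(rnorm(2L * n_ind * length(cols)), 2L * n_ind, length(cols))
      Zl <- E
      if (rho_k > 0 && length(cols) > 1L) {
        for (j in 2:length(cols))
          Zl[, j] <- rho_k * Zl[, j - 1L] + ar_scale * E[, j]
      }
      H <- Zl < rep(thr[cols], each = 2L * n_ind)
      X[, cols] <- H[1:n_ind, , drop = FALSE] +
        H[(n_ind + 1L):(2L * n_ind), , drop = FALSE]
    }
  })
  variants$maf <- maf
  genotype_panel(X, variants)
}

#' Simulate a quantitative GWAS trait with annotation-stratified effects
#'
#' Baseline effects hit a random fraction `pi_b` of all variants; each topic
#' annotation adds effects to a fraction `pi_k[k]` of its member variants.
#' Genetic values are computed on standardised genotypes and all effects are
#' rescaled so the realised genetic-variance fraction equals `h2` exactly
#' (the residual is orthogonalised against the genetic value). Marginal
#' summary statistics come from per-variant simple regression of the
#' phenotype on the standardised dosages.
#'
#' @param genotypes A [genotype_panel()].
#' @param annotations Variants x K binary matrix (or
#'   `scads_variant_annotation`), or NULL for baseline-only traits.
#' @param pi_b Baseline causal fraction.
#' @param pi_k Per-topic additional causal fraction (length K).
#' @param h2 Trait heritability in \[0, 1).
#' @param seed Seed.
#' @return List with `sumstats` (tibble `SNP`, `A1`, `A2`, `N`, `Z`) and
#'   `truth` (class `scads_gwas_truth`: scaled `beta0`, `beta_k`, total
#'   `beta`, per-variant heritability `h_p`, phenotype `y`, parameters).
#' @export
simulate_gwas <- function(genotypes, annotations = NULL, pi_b, pi_k = NULL,
                          h2, seed = 1L) {
  stopifnot(inherits(genotypes, "scads_genotypes"),
            pi_b >= 0, pi_b <= 1, h2 >= 0, h2 < 1)
  if (inherits(annotations, "scads_variant_annotation"))
    annotations <- annotations$A
  A <- if (is.null(annotations)) NULL else as.matrix(annotations)
  K <- if (is.null(A)) 0L else ncol(A)
  if (K > 0L && is.null(pi_k)) pi_k <- rep(0, K)
  if (K > 0L) stopifnot(length(pi_k) == K, all(pi_k >= 0))
  X <- genotypes$X
  n <- nrow(X); P <- ncol(X)

  with_seed(seed, {
    draw_effects <- function() {
      beta0 <- ifelse(runif(P) < pi_b, rnorm(P), 0)
      beta_k <- matrix(0, P, max(K, 1L))
      if (K > 0L) {
        for (k in seq_len(K)) {
          member <- A[, k] == 1L
          hit <- member & (runif(P) < pi_k[k])
          beta_k[hit, k] <- rnorm(sum(hit))
        }
      }
      list(beta0 = beta0, beta_k = beta_k)
    }
    eff <- draw_effects()
    beta <- eff$beta0 + rowSums(eff$beta_k)
    if (h2 > 0 && all(beta == 0)) {
      eff <- draw_effects()
      beta <- eff$beta0 + rowSums(eff$beta_k)
      if (all(beta == 0))
        stop_format("no causal variants drawn; increase pi_b or P")
    }

    eps <- rnorm(n)
    if (h2 > 0) {
      idx <- which(beta != 0)
      Xc <- scale(X[, idx, drop = FALSE])
      Xc[, attr(Xc, "scaled:scale") == 0] <- 0
      g <- as.numeric(Xc %*% beta[idx])
      g <- g - mean(g)
      sc <- sqrt(h2) / sd(g)
      g <- g * sc
      eff$beta0 <- eff$beta0 * sc
      eff$beta_k <- eff$beta_k * sc
      beta <- beta * sc
      e0 <- eps - mean(eps)
      e0 <- e0 - g * (sum(e0 * g) / sum(g^2))  # orthogonalise
      y <- g + e0 * sqrt(1 - h2) / sd(e0)
    } else {
      g <- rep(0, n)
      y <- (eps - mean(eps)) / sd(eps)
    }
  })

  r <- suppressWarnings(as.numeric(cor(X, y)))
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -0.999999), 0.999999)
  Z <- r * sqrt(n - 2) / sqrt(1 - r^2)
  sumstats <- tibble(SNP = genotypes$variants$id,
                     A1 = genotypes$variants$a1,
                     A2 = genotypes$variants$a2,
                     N = n, Z = Z)
  truth <- structure(list(beta0 = eff$beta0, beta_k = eff$beta_k,
                          beta = beta, h_p = beta^2, y = y, g = g,
                          params = list(pi_b = pi_b, pi_k = pi_k, h2 = h2,
                                        n = n, P = P, seed = seed)),
                     class = "scads_gwas_truth")
  list(sumstats = sumstats, truth = truth)
}

#' True topic enrichments implied by a simulated trait
#'
#' `e_k = (mean per-variant heritability inside A_k) / (mean per-variant
#' heritability overall)`, from the realised effect sizes. All-null traits
#' (zero heritability) have enrichment 1 by convention.
#'
#' @param truth A `scads_gwas_truth`.
#' @param annotations Variants x K binary matrix (or
#'   `scads_variant_annotation`).
#' @return Numeric vector of true enrichments.
#' @export
true_topic_enrichment <- function(truth, annotations) {
  if (inherits(annotations, "scads_variant_annotation"))
    annotations <- annotations$A
  A <- as.matrix(annotations)
  h <- truth$h_p
  overall <- mean(h)
  if (overall == 0) return(rep(1, ncol(A)))
  vapply(seq_len(ncol(A)), function(k) {
    m <- A[, k] == 1L
    if (!any(m)) return(1)
    mean(h[m]) / overall
  }, numeric(1))
}

#' Simulate a suite of null GWAS traits
#'
#' Independent traits with baseline-only effects (`pi_k = 0` for every
#' topic): no annotation is enriched, so the true enrichment is 1 for every
#' topic and every cell's true score is 1.
#'
#' @param genotypes A [genotype_panel()].
#' @param annotations Topic annotations (used only to fix K; no effects are
#'   placed on them).
#' @param n_traits Number of traits.
#' @param pi_b Baseline causal fraction (default 2.5e-4).
#' @param h2 Trait heritability (default 0.5).
#' @param seed Base seed; trait t uses `seed + t`.
#' @return List of [simulate_gwas()] results, one per trait.
#' @export
simulate_null_suite <- function(genotypes, annotations, n_traits = 200L,
                                pi_b = 2.5e-4, h2 = 0.5, seed = 1L) {
  if (inherits(annotations, "scads_variant_annotation"))
    annotations <- annotations$A
  K <- ncol(annotations)
  purrr::map(seq_len(n_traits), function(t) {
    simulate_gwas(genotypes, annotations, pi_b = pi_b,
                  pi_k = rep(0, K), h2 = h2, seed = seed + t)
  })
}

#' Simulate single-cell accessibility by Bernoulli pseudobulk sampling
#'
#' For cell type c the accessibility probability of peak j is
#' `p_jc = X_jc / sum_j X_jc * (s * 0.5 * (1 - r)) + r * (s / J) * 0.5`,
#' capped at 0.9; each cell draws two independent Bernoulli haplotypes per
#' peak, giving accessibility counts in \{0, 1, 2\}.
#'
#' @param X Peaks x cell-types pseudobulk count matrix (column names are the
#'   cell-type labels).
#' @param n_cells Cells per type (scalar or per-type vector).
#' @param s Target sequencing depth per cell.
#' @param r Background noise rate in \[0, 1\].
#' @param seed Seed.
#' @return List with `counts` (cells x peaks matrix in \{0, 1, 2\}, row
#'   names like `Mono_1`), `labels`, `p` (peaks x types probability matrix)
#'   and `n_capped` (peaks hitting the 0.9 cap, per type).
#' @export
simulate_scatac_bernoulli <- function(X, n_cells, s = 30000, r = 0.3,
                                      seed = 1L) {
  X <- as.matrix(X)
  stopifnot(all(X >= 0), r >= 0, r <= 1)
  J <- nrow(X); C <- ncol(X)
  types <- colnames(X) %||% paste0("type", seq_len(C))
  if (length(n_cells) == 1L) n_cells <- rep(n_cells, C)
  stopifnot(length(n_cells) == C)
  p_raw <- sweep(X, 2L, colSums(X), "/") * (s * 0.5 * (1 - r)) +
    r * (s / J) * 0.5
  n_capped <- colSums(p_raw > 0.9)
  p <- pmin(p_raw, 0.9)
  colnames(p) <- types
  total <- sum(n_cells)
  with_seed(seed, {
    counts <- matrix(0L, total, J)
    labels <- character(total)
    row <- 1L
    for (c in seq_len(C)) {
      for (i in seq_len(n_cells[c])) {
        counts[row, ] <- (runif(J) < p[, c]) + (runif(J) < p[, c])
        labels[row] <- sprintf("%s_%d", types[c], i)
        row <- row + 1L
      }
    }
    rownames(counts) <- labels
  })
  list(counts = counts, labels = labels, p = p, n_capped = n_capped)
}
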