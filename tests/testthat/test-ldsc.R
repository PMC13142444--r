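test_that("LD scores match the no-LD limit and containment bound", {
  ## independent variants: lA ~ annotation indicator (self r2 = 1)
  withr::with_seed(41, X <- matrix(rbinom(200 * 30, 2, 0.3), 200, 30))
  panel <- toy_panel(X, spacing = 1e7)  # every variant outside every window
  A <- cbind(matrix(rbinom(30, 1, 0.5)))
  ld <- compute_ld_scores(panel, A)
  expect_equal(unname(ld$lA[, 1]), as.numeric(A[, 1]))
  expect_equal(ld$l_total, rep(1, 30))
  ## annotation of all variants equals the total LD score exactly
  panel2 <- toy_panel(X, spacing = 100)
  ld2 <- compute_ld_scores(panel2, cbind(rep(1, 30)))
  expect_equal(unname(ld2$lA[, 1]), ld2$l_total)
  ## subset annotations never exceed the total (without the bias
  ## adjustment, whose negative pair terms can break the inequality)
  ld3 <- compute_ld_scores(panel2, A, adjust = FALSE)
  expect_true(all(ld3$lA[, 1] <= ld3$l_total + 1e-12))
})

test_that("LD scores equal the brute-force double sum", {
  withr::with_seed(42, {
    sim <- simulate_genotypes(50, 60, block_size = 20, rho = 0.8, seed = 7)
    A <- cbind(a = rbinom(60, 1, 0.4), b = rbinom(60, 1, 0.2))
  })
  for (adjust in c(TRUE, FALSE)) {
    ld <- compute_ld_scores(sim, A, window_bp = 12000, adjust = adjust)
    bf <- brute_ld_scores(sim, A, window_bp = 12000, adjust = adjust)
    expect_equal(unname(ld$lA), bf$lA, tolerance = 1e-12)
    expect_equal(ld$l_total, bf$l_total, tolerance = 1e-12)
  }
  ## window logic with a hand-checkable 3-variant panel
  X3 <- matrix(c(0L,1L,2L,2L,1L,0L, 1L,1L,2L,0L,2L,0L, 2L,0L,1L,1L,0L,2L),
               6, 3)
  p3 <- toy_panel(X3, spacing = 1000)
  ld3 <- compute_ld_scores(p3, cbind(c(1, 1, 1)), window_bp = 1000)
  r12 <- cor(X3[, 1], X3[, 2])^2; r12 <- r12 - (1 - r12) / 4
  r23 <- cor(X3[, 2], X3[, 3])^2; r23 <- r23 - (1 - r23) / 4
  expect_equal(unname(ld3$lA[, 1]), c(1 + r12, 1 + r12 + r23, 1 + r23),
               tolerance = 1e-12)
  ## monomorphic variants contribute zero
  X3b <- X3; X3b[, 2] <- 1L
  ldm <- compute_ld_scores(toy_panel(X3b, spacing = 1000),
                           cbind(c(1, 1, 1)), window_bp = 1000)
  expect_equal(unname(ldm$lA[2, 1]), 0)
  expect_error(compute_ld_scores(toy_panel(X3[1:2, ]), cbind(c(1, 1, 1))),
               "3 individuals")
})

test_that("sldsc point estimates are invariant to consistent duplication", {
  withr::with_seed(43, {
    sim <- simulate_genotypes(300, 400, block_size = 40, rho = 0.8, seed = 2)
    A <- cbind(rep(c(1, 0), each = 200))
    gw <- simulate_gwas(sim, A, pi_b = 0.02, pi_k = 0.2, h2 = 0.5, seed = 3)
  })
  ld <- compute_ld_scores(sim, A)
  f <- sldsc_fit(gw$sumstats$Z, 300, ld$lA[, 1], ld$l_total, A[, 1],
                 n_blocks = 20)
  fd <- sldsc_fit(rep(gw$sumstats$Z, 2), 300, rep(ld$lA[, 1], 2),
                  rep(ld$l_total, 2), rep(A[, 1], 2), n_blocks = 20)
  expect_equal(fd$e_hat, f$e_hat, tolerance = 1e-10)
  expect_equal(fd$tau, f$tau, tolerance = 1e-12)
  expect_error(sldsc_fit(gw$sumstats$Z, 300, ld$lA[, 1], ld$l_total,
                         rep(0, 400)), "empty")
})

test_that("sldsc recovers extreme enrichment and stays near 1 under the null", {
  ## all heritability inside the annotation (M_k / M = 0.1, h2 = 0.5)
  withr::with_seed(44, {
    sim <- simulate_genotypes(800, 2000, block_size = 50,
                              rho = rep(c(0.4, 0.95), 20), seed = 5)
  })
  A <- cbind(rep(c(1, 0), c(200, 1800)))
  gw <- simulate_gwas(sim, A, pi_b = 0, pi_k = 0.5, h2 = 0.5, seed = 6)
  ld <- compute_ld_scores(sim, A)
  f <- sldsc_fit(gw$sumstats$Z, 800, ld$lA[, 1], ld$l_total, A[, 1],
                 n_blocks = 40)
  expect_gt(f$e_hat, 5)
  expect_lt(f$p, 0.05)

  ## null traits: jackknife SE within a factor 2 of the empirical SD
  es <- ws <- numeric(20)
  for (s in 1:20) {
    gwn <- simulate_gwas(sim, A, pi_b = 0.02, pi_k = 0, h2 = 0.5,
                         seed = 100 + s)
    fn <- sldsc_fit(gwn$sumstats$Z, 800, ld$lA[, 1], ld$l_total, A[, 1],
                    n_blocks = 40)
    es[s] <- fn$e_hat; ws[s] <- fn$se
  }
  ratio <- mean(ws) / sd(es)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
  ## and the estimates centre near 1
  expect_lt(abs(mean(es) - 1), 2 * sd(es) / sqrt(20) + 0.5)
})

test_that("enrichment covariance uses the annotation correlation", {
  ## disjoint equal halves: correlation -1
  A <- cbind(a = rep(c(1, 0), each = 10), b = rep(c(0, 1), each = 10))
  C <- enrichment_covariance(c(2, 3), A)
  expect_equal(C[1, 2], -6)
  expect_equal(diag(C), c(4, 9), ignore_attr = TRUE)
  ## identical annotations: cov = w_k w_m
  A2 <- cbind(A[, 1], A[, 1])
  expect_equal(enrichment_covariance(c(2, 3), A2)[1, 2], 6)
  ## constant annotation: zero off-diagonal with warning
  A3 <- cbind(A[, 1], rep(1, 20))
  expect_warning(C3 <- enrichment_covariance(c(2, 3), A3), "constant")
  expect_equal(C3[1, 2], 0)
  expect_equal(diag(C3), c(4, 9), ignore_attr = TRUE)
  ## symmetry with unit-diagonal correlation structure
  withr::with_seed(45, A4 <- matrix(rbinom(120, 1, 0.4), 30, 4))
  w4 <- runif(4, 0.5, 2)
  C4 <- enrichment_covariance(w4, A4)
  expect_equal(C4, t(C4))
  expect_equal(cov2cor(C4), cor(A4), ignore_attr = TRUE)
})

test_that("shrinkage has the right limits and matches quadrature", {
  ## tiny noise: posterior means stay at the estimates
  e <- c(1.5, 0.7, 3)
  out <- shrink_enrichments(e, rep(1e-6, 3))
  expect_equal(out, e, tolerance = 1e-3)
  ## exact null fixed point
  expect_equal(shrink_enrichments(rep(1, 10), rep(0.5, 10)), rep(1, 10))
  ## single-topic input is still defined
  expect_length(shrink_enrichments(2, 0.5), 1)
  ## one-sided components can carry a common positive shift
  expect_true(all(shrink_enrichments(rep(3, 6), rep(1.5, 6)) > 2))

  ## noisy nulls shrink to 1, precise signal survives; check against a
  ## numerical-integration oracle of the posterior mean under the same
  ## symmetric prior
  e2 <- c(rep(1, 20) + withr::with_seed(46, rnorm(20, 0, 0.2)) * 5, 11)
  w2 <- c(rep(5, 20), 0.5)
  out2 <- shrink_enrichments(e2, w2, mixcompdist = "uniform")
  expect_true(all(abs(out2[1:20] - 1) < 1))
  expect_gt(out2[21], 9)

  ## quadrature oracle: recompute the posterior mean by numeric integration
  ## under the same uniform-mixture prior with EM-fitted weights
  d <- e2 - 1
  a_min <- min(w2) / 10
  a_max <- max(max(abs(d)) + 3 * max(w2), a_min * 2)
  a_grid <- a_min * 2^(0:ceiling(log2(a_max / a_min)))
  lik <- sapply(a_grid, function(a)
    (pnorm((a - d) / w2) - pnorm((-a - d) / w2)) / (2 * a))
  pi_m <- rep(1 / ncol(lik), ncol(lik))
  for (it in 1:2000) {
    r <- lik * rep(pi_m, each = length(d)); r <- r / rowSums(r)
    pin <- colMeans(r)
    if (max(abs(pin - pi_m)) < 1e-12) { pi_m <- pin; break }
    pi_m <- pin
  }
  post_quad <- sapply(seq_along(d), function(k) {
    grid <- seq(-a_max, a_max, length.out = 40001)
    step <- grid[2] - grid[1]
    prior <- rep(0, length(grid))
    for (m in seq_along(a_grid))
      prior <- prior + pi_m[m] *
        (abs(grid) <= a_grid[m]) / (2 * a_grid[m]) * step
    wgt <- prior * dnorm(d[k], grid, w2[k])
    sum(wgt * grid) / sum(wgt)
  })
  expect_equal(out2 - 1, post_quad, tolerance = 0.02)

  ## sign preservation under symmetric components: the posterior mean
  ## never crosses zero
  withr::with_seed(47, {
    dd <- rnorm(30, 0, 2)
    ww <- runif(30, 0.2, 3)
  })
  oo <- shrink_enrichments(1 + dd, ww, mixcompdist = "uniform") - 1
  expect_true(all(oo * dd >= -1e-12))
})
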