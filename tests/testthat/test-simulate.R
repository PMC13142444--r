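test_that("open masks cover every region and support clustering", {
  I <- simulate_open_masks(3, 500, p_open = 0.3, seed = 1)
  expect_true(all(colSums(I) >= 1))
  expect_identical(I, simulate_open_masks(3, 500, p_open = 0.3, seed = 1))
  ## cluster-level draws are constant within clusters
  Ic <- simulate_open_masks(2, 100, p_open = 0.5, cluster_size = 10,
                            seed = 2)
  for (c in seq_len(10)) {
    cols <- ((c - 1) * 10 + 1):(c * 10)
    expect_equal(length(unique(Ic[1, cols])), 1)
  }
})

test_that("topic profiles honour the open/closed rate ratio", {
  masks <- simulate_open_masks(2, 400, p_open = 0.4, seed = 3)
  ## cv = 0: every open rate is exactly ratio x every closed rate
  p0 <- simulate_topic_profiles(2, 400, masks, cv = 0, seed = 4)
  for (k in 1:2) {
    ratio <- unique(p0[k, masks[k, ] == 1]) / unique(p0[k, masks[k, ] == 0])
    expect_equal(ratio, 7.25, tolerance = 1e-12)
  }
  ## expected rates sum to ~1 per topic
  expect_equal(unname(rowSums(p0)), c(1, 1), tolerance = 1e-9)
  ## cv = 0.2, large J: empirical mean ratio within 10% of 7.25
  masks2 <- simulate_open_masks(2, 10000, p_open = 0.4, seed = 5)
  p2 <- simulate_topic_profiles(2, 10000, masks2, cv = 0.2, seed = 6)
  emp <- mean(p2[1, masks2[1, ] == 1]) / mean(p2[1, masks2[1, ] == 0])
  expect_equal(emp, 7.25, tolerance = 0.1)
  ## determinism and error on negative cv
  expect_identical(p2, simulate_topic_profiles(2, 10000, masks2, cv = 0.2,
                                               seed = 6))
  expect_error(simulate_topic_profiles(2, 400, masks, cv = -1), "cv")
})

test_that("simulated scATAC depths follow the log-normal depth law", {
  masks <- simulate_open_masks(2, 300, p_open = 0.4, seed = 7)
  prof <- simulate_topic_profiles(2, 300, masks, cv = 0, seed = 8)
  sim <- simulate_scatac(prof, n_cells = 3000, seed = 9)
  depth <- Matrix::rowSums(sim$counts$counts)
  expect_equal(median(depth) / 20000, 1, tolerance = 0.05)
  expect_equal(sd(log(sim$truth$depths)), 0.173, tolerance = 0.02)
  ## truth loadings are a valid simplex and dimensions agree
  expect_equal(rowSums(sim$truth$Lp), rep(1, 3000), tolerance = 1e-12)
  expect_identical(dim(sim$counts$counts), c(3000L, 300L))
})

test_that("K = 1 counts match the profile up to multinomial noise", {
  masks <- matrix(1L, 1, 50)
  prof <- simulate_topic_profiles(1, 50, masks, cv = 0, seed = 10)
  sim <- simulate_scatac(prof, n_cells = 400, seed = 11,
                         depth_median = 5000)
  frac <- Matrix::colSums(sim$counts$counts) / sum(sim$counts$counts)
  expect_equal(unname(frac), unname(prof[1, ] / sum(prof[1, ])),
               tolerance = 0.05)
})

test_that("block-LD genotypes have the advertised correlation structure", {
  ## independence at rho = 0
  g0 <- simulate_genotypes(400, 40, block_size = 10, rho = 0, seed = 12)
  cors <- abs(cor(g0$X)[cbind(1:39, 2:40)])
  expect_lt(mean(cors, na.rm = TRUE), 3 / sqrt(400))
  ## AR decay at rho = 0.9
  g9 <- simulate_genotypes(800, 30, block_size = 30, rho = 0.9, seed = 13)
  C <- cor(g9$X)
  adj <- mean(C[cbind(1:29, 2:30)])
  far <- mean(C[cbind(1:20, 11:30)])
  expect_gt(adj, 0.5)
  expect_gt(adj, far + 0.2)
  ## allele frequencies respect maf_range (up to sampling error)
  af <- colMeans(g9$X) / 2
  expect_true(all(af > 0.01 & af < 0.6))
  expect_true(all(g9$X %in% 0:2))
  expect_identical(g9$X, simulate_genotypes(800, 30, block_size = 30,
                                            rho = 0.9, seed = 13)$X)
})

test_that("simulated traits hit the target heritability exactly", {
  g <- simulate_genotypes(300, 500, block_size = 50, seed = 14)
  A <- cbind(rbinom(500, 1, 0.3))
  gw <- simulate_gwas(g, A, pi_b = 0.02, pi_k = 0.1, h2 = 0.4, seed = 15)
  expect_equal(var(gw$truth$g) / var(gw$truth$y), 0.4, tolerance = 1e-12)
  ## annotation-only effects respect membership
  expect_true(all(gw$truth$beta_k[A[, 1] == 0, 1] == 0))
  ## null trait: phenotype independent of genotype, Z ~ standard normal
  gw0 <- simulate_gwas(g, A, pi_b = 0.02, pi_k = 0, h2 = 0, seed = 16)
  expect_equal(var(gw0$truth$y), 1, tolerance = 1e-12)
  ## correlated variants leave few effective draws; loose centring check
  expect_lt(abs(mean(gw0$sumstats$Z)), 0.3)
})

test_that("null GWAS z-scores are standard normal at h2 = 0", {
  g <- simulate_genotypes(200, 10000, block_size = 100, rho = 0,
                          maf_range = c(0.1, 0.5), seed = 17)
  gw <- simulate_gwas(g, NULL, pi_b = 0, pi_k = NULL, h2 = 0, seed = 18)
  ks <- suppressWarnings(ks.test(gw$sumstats$Z, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("baseline causal counts follow the expected Poisson law", {
  ## pi_b = 2.5e-4 over 40,000 variants: expect ~10 causal
  g <- simulate_genotypes(40, 40000, block_size = 200, seed = 19)
  counts <- sapply(1:8, function(s) {
    gw <- simulate_gwas(g, NULL, pi_b = 2.5e-4, h2 = 0.5, seed = 500 + s)
    sum(gw$truth$beta0 != 0)
  })
  expect_true(all(counts >= qpois(0.005, 10) & counts <= qpois(0.995, 10)))
})

test_that("the null suite has unit true enrichment everywhere", {
  g <- simulate_genotypes(100, 300, block_size = 50, seed = 20)
  A <- cbind(a = rbinom(300, 1, 0.3), b = rbinom(300, 1, 0.3))
  suite <- simulate_null_suite(g, A, n_traits = 4, pi_b = 0.02, seed = 21)
  expect_length(suite, 4)
  ## no annotation-conditional effects are drawn under the null design
  for (tr in suite)
    expect_true(all(tr$truth$beta_k == 0))
  ## distinct traits get distinct z-vectors
  expect_false(identical(suite[[1]]$sumstats$Z, suite[[2]]$sumstats$Z))
})

test_that("Bernoulli accessibility probabilities follow the stated formula", {
  J <- 1000
  X <- matrix(1, J, 2, dimnames = list(NULL, c("Mono", "Bcell")))
  out <- simulate_scatac_bernoulli(X, n_cells = 10, s = 300, r = 0.3,
                                   seed = 22)
  ## uniform pseudobulk: p = (1/J)(s*0.5*0.7) + 0.3*(s/J)*0.5 = 0.15
  expect_equal(unname(out$p[1, ]), c(0.15, 0.15), tolerance = 1e-12)
  expect_true(all(out$counts %in% 0:2))
  expect_equal(out$labels[1], "Mono_1")
  expect_equal(out$labels[11], "Bcell_1")
  ## r = 1: probability independent of the pseudobulk
  X2 <- X; X2[1, 1] <- 1000
  out1 <- simulate_scatac_bernoulli(X2, n_cells = 2, s = 300, r = 1,
                                    seed = 23)
  expect_equal(unique(as.vector(out1$p)), 300 / (2 * J))
  ## extreme peaks are capped at 0.9
  X3 <- matrix(c(1e6, rep(1, J - 1)), J, 1)
  out3 <- simulate_scatac_bernoulli(X3, n_cells = 2, s = 3000, r = 0.3,
                                    seed = 24)
  expect_equal(max(out3$p), 0.9)
  expect_equal(unname(out3$n_capped), 1)
})
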