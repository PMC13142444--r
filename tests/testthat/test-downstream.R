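make_scored_counts <- function() {
  ## 10 cells, 4 regions on chr1; cell scores increase with index.
  ## region 2 accessibility grows with score; per-cell totals are constant
  ## so CPM is linear in the bin index.
  X <- matrix(0L, 10, 4)
  for (i in 1:10) X[i, ] <- c(5L, i * 2L, 4L, 31L - 2L * i)
  regions <- tibble::tibble(chrom = "chr1",
                            start = c(0, 1000, 2000, 3000),
                            end = c(500, 1500, 2500, 3500))
  counts <- cell_region_matrix(X, regions, sprintf("c%02d", 1:10))
  scores <- tibble::tibble(barcode = sprintf("c%02d", 1:10),
                           score = seq(0.5, 2.3, length.out = 10))
  list(counts = counts, scores = scores)
}

test_that("variant-score correlation bins cells and computes CPM as defined", {
  fx <- make_scored_counts()
  variants <- tibble::tibble(id = c("v_lin", "v_out"), chrom = "chr1",
                             pos = c(1250, 900000))
  res <- variant_score_correlation(fx$counts, fx$scores, variants,
                                   n_bins = 5, cpm_min = 0, min_bins = 2)
  ## monotone accessibility vs score -> r = 1 (2 cells per bin, linear sums)
  expect_equal(res$pearson_r[res$id == "v_lin"], 1, tolerance = 1e-9)
  ## variant outside every region window: zero CPM, not retained at cpm_min=5
  res2 <- variant_score_correlation(fx$counts, fx$scores, variants,
                                    n_bins = 5, cpm_min = 5, min_bins = 2)
  expect_false(res2$retained[res2$id == "v_out"])
  expect_true(is.na(res2$pearson_r[res2$id == "v_out"]))

  ## CPM definition: accessibility / bin library * 1e6
  cpm <- res$cpm[[which(res$id == "v_lin")]]
  lib1 <- sum(fx$counts$counts[1:2, ])  # lowest-score bin, 2 cells
  acc1 <- sum(fx$counts$counts[1:2, 2]) # region containing pos 1250
  expect_equal(cpm[1], acc1 / lib1 * 1e6)

  ## depth-rescaling invariance of the correlation
  X2 <- fx$counts$counts * 3
  counts2 <- cell_region_matrix(X2, fx$counts$regions, fx$counts$barcodes)
  res3 <- variant_score_correlation(counts2, fx$scores, variants,
                                    n_bins = 5, cpm_min = 0, min_bins = 2)
  expect_equal(res3$pearson_r[1], res$pearson_r[1], tolerance = 1e-9)

  expect_error(variant_score_correlation(fx$counts, fx$scores[1:3, ],
                                         variants, n_bins = 5),
               "fewer")
})

test_that("variants are classified by PIP and correlation sign", {
  cors <- tibble::tibble(id = c("a", "b", "c", "d"),
                         pearson_r = c(-0.978, 0.9, 0.1, NA),
                         retained = c(TRUE, TRUE, TRUE, FALSE))
  pip <- tibble::tibble(id = c("a", "b", "c", "d"),
                        pip = c(0.999, 0.25, 0.5, 0.8))
  out <- classify_variants(pip, cors)
  expect_equal(out$group[out$id == "a"], "negative")
  expect_false("b" %in% out$id)  # below the PIP threshold
  expect_equal(out$group[out$id == "c"], "none")
  expect_equal(out$group[out$id == "d"], "none")
  ## partitions are exclusive and exhaustive over the PIP-passing set
  expect_equal(sort(out$id), c("a", "c", "d"))
  expect_true(all(out$group %in% c("positive", "negative", "none")))
})

test_that("nearest gene handles containment, ties and empty chromosomes", {
  genes <- tibble::tibble(gene = c("G1", "G2", "G3"),
                          chrom = c("chr1", "chr1", "chr2"),
                          start = c(1000, 5000, 0),
                          end = c(2000, 6000, 100))
  ## inside G1
  v1 <- tibble::tibble(id = "x", chrom = "chr1", pos = 1500)
  out1 <- nearest_gene(v1, genes)
  expect_equal(out1$gene, "G1")
  expect_equal(out1$distance, 0)
  ## equidistant between G1 end (0-based 1999) and G2 start: tie
  genes$start[2] <- 4999
  v2 <- tibble::tibble(id = "y", chrom = "chr1", pos = 3500)
  out2 <- nearest_gene(v2, genes)
  expect_setequal(out2$gene, c("G1", "G2"))
  ## chromosome with no genes -> no assignment
  v3 <- tibble::tibble(id = "z", chrom = "chrX", pos = 100)
  expect_equal(nrow(nearest_gene(v3, genes)), 0)

  ## random instance vs exhaustive scan
  withr::with_seed(31, {
    gt <- tibble::tibble(gene = paste0("g", 1:20),
                         chrom = sample(c("chr1", "chr2"), 20, TRUE),
                         start = sample.int(1e5, 20))
    gt$end <- gt$start + sample.int(5000, 20)
    vs <- tibble::tibble(id = paste0("v", 1:15),
                         chrom = sample(c("chr1", "chr2"), 15, TRUE),
                         pos = sample.int(1e5, 15))
  })
  out <- nearest_gene(vs, gt)
  for (i in seq_len(nrow(vs))) {
    g <- gt[gt$chrom == vs$chrom[i], ]
    d <- pmax(0, pmax(g$start - (vs$pos[i] - 1), (vs$pos[i] - 1) - (g$end - 1)))
    expect_setequal(out$gene[out$id == vs$id[i]], g$gene[d == min(d)])
  }
})

test_that("regulon enrichment matches the hypergeometric tail", {
  bg <- paste0("g", 1:1000)
  regs <- list(R1 = paste0("g", 1:50), R0 = paste0("g", 900:949))
  targets <- c(paste0("g", 1:5), paste0("g", 100:104))  # overlap 5 with R1
  out <- regulon_enrichment(targets, regs, bg)
  ## direct hypergeometric upper-tail summation
  p_manual <- sum(dhyper(5:10, 50, 950, 10))
  expect_equal(out$p[out$tf == "R1"], p_manual, tolerance = 1e-12)
  ## zero overlap -> p = 1
  expect_equal(out$p[out$tf == "R0"], 1)
  ## regulon = background is uninformative
  out2 <- regulon_enrichment(targets, list(All = bg), bg)
  expect_equal(out2$p, 1)
  ## empty target set -> all p = 1
  out3 <- regulon_enrichment(character(0), regs, bg)
  expect_true(all(out3$p == 1))
  ## BH is applied across regulons
  expect_equal(out$fdr, p.adjust(out$p, "BH")[order(out$p)])
})

test_that("fine-mapping priors export only significant topics", {
  variants <- tibble::tibble(id = paste0("rs", 1:4), chrom = "chr1",
                             pos = c(150, 250, 350, 450))
  regions <- tibble::tibble(chrom = "chr1", start = c(100, 300),
                            end = c(200, 400))
  I <- rbind(c(1, 1), c(1, 0), c(0, 1))
  ann <- build_variant_annotation(I, regions, variants)
  enr <- tibble::tibble(topic = c("topic1", "topic2", "topic3"),
                        p = c(0.01, 0.2, 0.04))
  dir <- withr::local_tempdir()
  out <- export_finemapping_priors(enr, ann, file.path(dir, "prior.tsv"))
  expect_equal(nrow(out), 4)            # one row per variant
  expect_setequal(setdiff(names(out), c("SNP", "CHR", "BP")),
                  c("topic1", "topic3"))
  enr$p <- c(0.9, 0.8, 0.7)
  expect_warning(out2 <- export_finemapping_priors(enr, ann,
                                                   file.path(dir, "p2.tsv")),
                 "no topic")
  expect_equal(ncol(out2), 3)
})
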