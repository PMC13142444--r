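# scads

Single-cell ATAC-seq disease scores from GWAS summary statistics.

## What problem this solves

scATAC-seq captures reads in only a few percent of the regulatory regions
active in any one cell, so whether a given region is open in a given cell
is essentially unobservable — yet the disease relevance of a cell is
naturally defined through exactly that: the enrichment of per-variant trait
heritability inside the cell's open chromatin relative to the genome-wide
average. `scads` estimates this quantity for every cell by pooling
information in a low-dimensional space:

1. **Topic model** — the cell × region count matrix is decomposed by a
   grade-of-membership model (fitted as Poisson NMF by multiplicative EM):
   counts for cell *i* are multinomial with probabilities
   π<sub>ij</sub> = Σ<sub>k</sub> l<sub>ik</sub> f<sub>kj</sub>.
2. **Open-region annotations** — per topic, soft-assigned pseudobulk counts
   are tested against a GC-aware background rate (two-component mixture per
   GC bin; quasi-Poisson log₂-fold-change test; BH FDR < 0.05), and the
   open calls are projected to binary variant annotations A<sub>k</sub>.
3. **Heritability enrichment** — stratified LD-score regression of GWAS χ²
   statistics on annotation LD scores
   ℓ<sub>A,p</sub> = Σ<sub>q∈A</sub> r̃²<sub>pq</sub> gives, one topic at a
   time, the enrichment ê<sub>k</sub> with a block-jackknife SE
   w<sub>k</sub>, stabilised by empirical-Bayes shrinkage.
4. **Cell score** — with s<sub>k</sub> = Σ<sub>j</sub> I<sub>kj</sub>
   v<sub>j</sub> the variant-weighted open size of topic *k*,

   c&#770;<sub>i</sub> = Σ<sub>k</sub> l<sub>ik</sub> s<sub>k</sub> e<sub>k</sub> / Σ<sub>k</sub> l<sub>ik</sub> s<sub>k</sub>,

   a convex combination of topic enrichments, with analytic variance
   Var(c&#770;<sub>i</sub>) = Σ<sub>k,m</sub> (l<sub>ik</sub>s<sub>k</sub>)(l<sub>im</sub>s<sub>m</sub>) Cov(e<sub>k</sub>,e<sub>m</sub>) / S<sub>i</sub>²,
   Cov(e<sub>k</sub>,e<sub>m</sub>) = w<sub>k</sub>w<sub>m</sub> Cor(A<sub>k</sub>,A<sub>m</sub>),
   a one-sided z-test against background (score 1) and BH FDR across cells.

The package is aimed at statistical geneticists and single-cell
bioinformaticians who have a peak × cell count matrix and LDSC-style GWAS
summary statistics and want calibrated per-cell disease-relevance scores,
plus the downstream analytics around them (variant accessibility/score
correlation over score bins, nearest-gene assignment, regulon Fisher
enrichment, fine-mapping prior export). It also ships the full synthetic
data stack — topic-model scATAC-seq counts, block-LD genotype panels,
annotation-stratified GWAS traits, a null-trait suite and a Bernoulli
pseudobulk accessibility simulator — so every stage is testable end to end
without external data.

## Worked example

A fully synthetic study, small enough to run in about a minute: 3 topics,
400 cells, 2,000 regions, 4,000 variants, 800 individuals, one topic's open
regions carrying 10× the baseline causal-variant fraction.

```r
library(scads)

genome <- simulate_genome(n_blocks = 40, variants_per_block = 100,
                          regions_per_block = 50, in_region_per_block = 10,
                          seed = 1)
masks  <- simulate_open_masks(3, nrow(genome$regions), p_open = 0.4,
                              cluster_size = 50, seed = 2)
prof   <- simulate_topic_profiles(3, nrow(genome$regions), masks,
                                  cv = 0.2, seed = 3)
atac   <- simulate_scatac(prof, n_cells = 400, seed = 4,
                          regions = genome$regions)
geno   <- simulate_genotypes(800, nrow(genome$variants), block_size = 100,
                             rho = seq(0.5, 0.95, length.out = 8), seed = 5,
                             variants = genome$variants)
truth  <- build_variant_annotation(masks, genome$regions, genome$variants)
trait  <- simulate_gwas(geno, truth, pi_b = 5e-3, pi_k = c(0.05, 0, 0),
                        h2 = 0.5, seed = 6)

res <- run_pipeline(list(counts = atac$counts, sumstats = trait$sumstats,
                         genotypes = geno, K = 3, seed = 7,
                         max_iter = 200, tol = 1e-6))
res$enrichment[, c("topic", "e_hat", "se", "p", "e_post", "genome_fraction")]
#> # A tibble: 3 × 6
#>   topic  e_hat    se      p e_post genome_fraction
#>   <chr>  <dbl> <dbl>  <dbl>  <dbl>           <dbl>
#> 1 topic1  3.64  2.48 0.287    3.25          0.0388
#> 2 topic2  3.34  3.60 0.516    3.21          0.0482
#> 3 topic3  6.78  3.05 0.0578   3.98          0.0565
glance(res$cell_scores)
#> # A tibble: 1 × 5
#>   n_cells n_scored n_significant mean_score n_topics_used
#>     <int>    <int>         <int>      <dbl>         <int>
#> 1     400      400             0       3.50             3
```

Fitted topics are identified only up to permutation, so "topic3" here is
the fitted counterpart of the causal simulated topic: it gets the largest
enrichment (ê = 6.8 ± 3.0; all three topics sit above 1 because their open
regions overlap the causal topic's). Each cell's score is its
loading-weighted mixture of the (shrunken) topic enrichments — here scores
average 3.5-fold enrichment, and no single cell is BH-significant at this
small sample size. Against the ground truth the ranking is recovered well:

```r
e_true <- true_topic_enrichment(trait$truth, truth)
ts <- true_cell_enrichment(atac$truth$L, masks, truth$v, e_true)
cor(res$cell_scores$score, ts, method = "spearman")
#> [1] 0.9123
```

`autoplot(res$enrichment)` and `autoplot(res$cell_scores)` give the
standard ggplot views; `tidy(res$fit)` / `glance(res$fit)` expose the topic
fit as tibbles. A thin command-line wrapper around `run_pipeline()` lives
at `inst/scripts/scads.R` (YAML config, `--seed`, `--out-dir`).

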