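test_that("heterozygosities and FIS match hand arithmetic", {
  g <- geno_matrix(matrix(c(0L, 1L, 1L, 2L), 4, 1, dimnames = list(NULL, "s")))
  het <- per_locus_heterozygosity(g)
  expect_equal(het$ho, 0.5)
  expect_equal(het$he, 8 / 7 * 0.5)
  fis <- inbreeding_coefficient(het)
  expect_equal(fis$fis, 1 - 0.5 / (8 / 7 * 0.5))
  # He = Ho -> FIS 0; Ho = 0 with He > 0 -> FIS 1
  expect_equal(inbreeding_coefficient(
    tibble::tibble(ho = 0.5, he = 0.5))$fis, 0)
  expect_equal(inbreeding_coefficient(
    tibble::tibble(ho = 0, he = 0.3))$fis, 1)
  mono <- geno_matrix(matrix(0L, 5, 1))
  h2 <- per_locus_heterozygosity(mono)
  expect_equal(h2$ho, 0)
  expect_equal(h2$he, 0)
})

test_that("allelic richness follows Hurlbert rarefaction", {
  # N = 4 alleles with counts (2, 2), g = 2: AR = 2 - 2 C(2,2)/C(4,2)
  g <- geno_matrix(matrix(c(1L, 1L), 2, 1), ids = c("x", "y"))
  ar <- allelic_richness(g, groups = c("p", "p"), rarefaction_size = 2)
  expect_equal(ar$ar, 2 - 2 * choose(2, 2) / choose(4, 2))
  # fixed SNP: AR = 1 exactly
  fixed <- geno_matrix(matrix(0L, 3, 1))
  expect_equal(allelic_richness(fixed, rep("p", 3), 2)$ar, 1)
  # both alleles at counts far above the draw size: AR approaches 2
  big <- geno_matrix(matrix(rep(1L, 200), 200, 1))
  expect_gt(allelic_richness(big, rep("p", 200), rarefaction_size = 50)$ar, 1.99)
  expect_error(allelic_richness(g, c("p", "p"), rarefaction_size = 1),
               "below 2")
})

test_that("welch_t reproduces t.test and its symmetry", {
  res <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  swapped <- welch_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p_value, res$p_value)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("Weir-Cockerham theta hits its fixed points", {
  # two groups fixed for alternate alleles -> theta = 1
  g <- geno_matrix(rbind(a = c(0L, 0L), b = c(0L, 0L),
                         c = c(2L, 2L), d = c(2L, 2L)))
  expect_equal(wc_fst(g, c("x", "x", "y", "y")), 1)
  # one panmictic group split at random -> theta near 0
  sim <- simulate_island_genotypes(island_model_spec(
    n_pops = 1, n_per_pop = 100, n_snps = 800, fst = 0, seed = 17))
  lab <- rep(c("u", "v"), 50)
  expect_lt(abs(wc_fst(sim$genotypes, lab)), 0.01)
})

test_that("statistics are invariant to allele flips and row order", {
  sim <- simulate_island_genotypes(island_model_spec(
    n_pops = 2, n_per_pop = 25, n_snps = 120, fst = 0.1, seed = 19))
  g <- sim$genotypes
  pops <- sim$metadata$population
  flip <- unclass(g)
  flipped_cols <- seq(1, ncol(flip), by = 2)
  flip[, flipped_cols] <- 2L - flip[, flipped_cols]
  gf <- geno_matrix(flip)
  expect_equal(wc_fst(gf, pops), wc_fst(g, pops))
  expect_equal(per_locus_heterozygosity(gf)$he, per_locus_heterozygosity(g)$he)
  expect_equal(tidy(amova(gf, pops, n_perm = 0))$sigma2,
               tidy(amova(g, pops, n_perm = 0))$sigma2)
  ord <- sample(n_ind(g))
  expect_equal(wc_fst(g[ord, ], pops[ord]), wc_fst(g, pops))
})

test_that("pairwise FST recovers simulated differentiation with p-values", {
  sim <- simulate_island_genotypes(island_model_spec(
    n_pops = 2, n_per_pop = 40, n_snps = 600, fst = 0.1, seed = 23))
  res <- pairwise_fst(sim$genotypes, sim$metadata, "population",
                      n_perm = 99, seed = 1)
  expect_equal(nrow(res), 1L)
  expect_equal(res$fst, 0.1, tolerance = 0.3)
  expect_lte(res$p_value, 0.02)
  # undersized group skipped with a warning
  meta3 <- sim$metadata
  meta3$population[1:2] <- "tiny"
  expect_warning(
    res3 <- pairwise_fst(sim$genotypes, meta3, "population", n_perm = 0),
    "skipped")
  expect_false("tiny" %in% c(res3$group1, res3$group2))
})

test_that("AMOVA matches the hand decomposition on the 4x1 fixture", {
  # two populations fixed for opposite alleles, all homozygous
  g <- geno_matrix(rbind(a = 0L, b = 0L, c = 2L, d = 2L))
  res <- tidy(amova(g, c("p", "p", "q", "q"), n_perm = 0))
  expect_equal(res$sigma2[3], 0)  # no within-individual variation
  expect_equal(res$percent[1], 100)
  expect_equal(sum(res$percent), 100)
})

test_that("AMOVA components equal the nested-ANOVA oracle on small cases", {
  withr::local_seed(7)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    L <- sample(1:3, 1)
    m <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
    pops <- sample(rep(c("p", "q"), length.out = n))
    if (length(unique(pops)) < 2) next
    g <- geno_matrix(m)
    got <- tidy(amova(g, pops, n_perm = 0))
    if (sum(abs(got$sigma2)) == 0) next
    want <- oracle_amova(g, pops)
    expect_equal(got$ssd, want$ssd, tolerance = 1e-10)
    expect_equal(got$sigma2, want$sigma2, tolerance = 1e-10)
    expect_equal(sum(got$percent), 100, tolerance = 1e-6)
  }
})

test_that("AMOVA near-zero among-population variance under panmixia", {
  sim <- simulate_island_genotypes(island_model_spec(
    n_pops = 1, n_per_pop = 60, n_snps = 400, fst = 0, seed = 29))
  lab <- rep(c("u", "v", "w"), each = 20)
  res <- tidy(amova(sim$genotypes, lab, n_perm = 0))
  expect_lt(abs(res$percent[1]), 2)
  clones <- geno_matrix(matrix(2L, 4, 3))  # zero variance at every level
  expect_error(amova(clones, c("p", "p", "q", "q"), n_perm = 0), "degenerate")
})

test_that("diversity_summary aggregates by group with SDs over SNPs", {
  sim <- simulate_island_genotypes(island_model_spec(
    n_pops = 2, n_per_pop = 20, n_snps = 100, fst = 0.05, seed = 37))
  div <- diversity_summary(sim$genotypes, sim$metadata, "continent")
  expect_equal(nrow(div), 2L)
  expect_true(all(div$he_mean > 0 & div$he_mean < 1))
  expect_true(all(div$he_sd >= 0))
  expect_true(all(div$ar_mean >= 1 & div$ar_mean <= 2))
  global <- diversity_summary(sim$genotypes)
  expect_equal(global$group, "all")
})
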