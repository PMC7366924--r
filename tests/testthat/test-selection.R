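test_that("allele counts by group are hand-checkable and exclude missing", {
  g <- geno_matrix(matrix(c(0L, 1L, 2L, 1L), 4, 1), ids = letters[1:4])
  cnt <- allele_counts_by_group(g, c("x", "x", "x", "y"))
  expect_equal(unname(cnt$n[, 1]), c(6, 2))
  expect_equal(unname(cnt$alt[, 1]), c(3, 1))
  gm <- geno_matrix(matrix(c(0L, NA, 2L, 1L), 4, 1), ids = letters[1:4])
  cntm <- allele_counts_by_group(gm, c("x", "x", "x", "y"))
  expect_equal(unname(cntm$n[, 1]), c(4, 2))
  expect_error(allele_counts_by_group(g, rep("x", 4)), "two groups")
})

test_that("a planted fixed difference is top-ranked and declared", {
  sim <- simulate_island_genotypes(island_model_spec(
    n_pops = 2, n_per_pop = 30, n_snps = 300, fst = 0.05, seed = 73))
  m <- unclass(sim$genotypes)
  m[sim$metadata$population == "pop1", 1] <- 0L
  m[sim$metadata$population == "pop2", 1] <- 2L
  cnt <- allele_counts_by_group(geno_matrix(m), sim$metadata$population)
  scan <- bayescan_fit(cnt, n_burnin = 500, n_sample = 500, thin = 2,
                       n_pilot = 3, pilot_len = 100, seed = 5)
  res <- tidy(scan)
  expect_equal(which.max(res$prob_included), 1L)
  expect_true(res$outlier[1])
  expect_gt(res$alpha_mean[1], 0)  # diversifying: positive locus effect
  expect_true(all(res$q_value >= 0 & res$q_value <= 1))
  # q-values non-decreasing when sorted by inclusion probability desc
  ord <- order(res$prob_included, decreasing = TRUE)
  expect_true(all(diff(res$q_value[ord]) > -1e-12))
})

test_that("two identical groups yield no outliers", {
  sim <- simulate_island_genotypes(island_model_spec(
    n_pops = 1, n_per_pop = 40, n_snps = 150, fst = 0, seed = 79))
  lab <- rep(c("u", "v"), 20)
  cnt <- allele_counts_by_group(sim$genotypes, lab)
  scan <- bayescan_fit(cnt, n_burnin = 300, n_sample = 300, thin = 2,
                       n_pilot = 2, pilot_len = 100, seed = 6)
  expect_equal(sum(tidy(scan)$outlier), 0L)
})

test_that("a homogenizing locus in a differentiated genome gets negative alpha", {
  sim <- simulate_island_genotypes(island_model_spec(
    n_pops = 2, n_per_pop = 40, n_snps = 200, fst = 0.25,
    maf_range = c(0.3, 0.5), seed = 83))
  m <- unclass(sim$genotypes)
  # planted balanced locus: identical intermediate frequencies in both groups
  m[, 1] <- rep(c(0L, 1L, 1L, 2L), 20)
  cnt <- allele_counts_by_group(geno_matrix(m), sim$metadata$population)
  scan <- bayescan_fit(cnt, n_burnin = 400, n_sample = 400, thin = 2,
                       n_pilot = 2, pilot_len = 100, seed = 7)
  expect_lt(tidy(scan)$alpha_mean[1], 0)
})

test_that("raising the prior odds of neutrality empties the outlier set", {
  sim <- simulate_island_genotypes(island_model_spec(
    n_pops = 2, n_per_pop = 25, n_snps = 120, fst = 0.1, seed = 89))
  cnt <- allele_counts_by_group(sim$genotypes, sim$metadata$population)
  expect_warning(
    scan <- bayescan_fit(cnt, prior_odds = 1e7, n_burnin = 300, n_sample = 300,
                         thin = 2, n_pilot = 2, pilot_len = 50, seed = 8),
    "near the prior")
  expect_equal(sum(tidy(scan)$outlier), 0L)
})

test_that("the scan is reproducible under a fixed seed", {
  sim <- simulate_island_genotypes(island_model_spec(
    n_pops = 2, n_per_pop = 20, n_snps = 80, fst = 0.1, seed = 97))
  cnt <- allele_counts_by_group(sim$genotypes, sim$metadata$population)
  s1 <- bayescan_fit(cnt, n_burnin = 200, n_sample = 200, thin = 2,
                     n_pilot = 2, pilot_len = 50, seed = 11)
  s2 <- bayescan_fit(cnt, n_burnin = 200, n_sample = 200, thin = 2,
                     n_pilot = 2, pilot_len = 50, seed = 11)
  expect_identical(tidy(s1), tidy(s2))
})

test_that("gene-window annotation applies the closed 200 kbp overlap rule", {
  snps <- tibble::tibble(snp_id = "s1", scaffold = "scafA", position = 500000L)
  genes <- tibble::tibble(
    scaffold = c("scafA", "scafA", "scafA", "scafB"),
    start = c(650000L, 710000L, 695000L, 650000L),
    end = c(660000L, 720000L, 705000L, 660000L),
    gene = c("inside", "outside", "straddle", "other_scaffold"))
  ann <- annotate_windows(snps, genes, flank = 200000)
  expect_setequal(ann$gene[!is.na(ann$gene)], c("inside", "straddle"))
  expect_equal(unique(ann$window_start), 300000)
  expect_equal(unique(ann$window_end), 700000)
  # window clipped at the scaffold origin
  near <- tibble::tibble(snp_id = "s2", scaffold = "scafA", position = 100L)
  ann2 <- annotate_windows(near, genes, flank = 200000)
  expect_equal(ann2$window_start, 1)
  # SNP without position skipped with a warning
  nopos <- tibble::tibble(snp_id = "s3", scaffold = "scafA",
                          position = NA_integer_)
  expect_warning(ann3 <- annotate_windows(nopos, genes), "without position")
  expect_equal(nrow(ann3), 0L)
})
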