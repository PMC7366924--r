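test_that("island model specs validate their fields", {
  expect_error(island_model_spec(2, 10, 100, fst = 1), "\\[0, 1\\)")
  expect_error(island_model_spec(2, 10, 100, fst = 0.1, maf_range = c(0, 0.5)),
               "maf_range")
  expect_error(island_model_spec(2, 10, 100, fst = 0.1,
                                 geno_missing_rate = 1), "missing rates")
})

test_that("generation is bit-reproducible under a fixed seed", {
  spec <- island_model_spec(3, 10, 50, fst = 0.05, geno_missing_rate = 0.1,
                            seed = 42)
  a <- simulate_island_genotypes(spec)
  b <- simulate_island_genotypes(spec)
  expect_identical(unclass(a$genotypes), unclass(b$genotypes))
  expect_identical(a$true_freq, b$true_freq)
  r1 <- simulate_read_assignments(hybrid_sim_spec(20, 1000, seed = 9))
  r2 <- simulate_read_assignments(hybrid_sim_spec(20, 1000, seed = 9))
  expect_identical(r1, r2)
})

test_that("fst = 0 gives undifferentiated populations (no Beta blow-up)", {
  sim <- simulate_island_genotypes(island_model_spec(
    n_pops = 2, n_per_pop = 300, n_snps = 400, fst = 0, seed = 3))
  expect_true(all(sim$true_freq[1, ] == sim$true_freq[2, ]))
  p1 <- allele_freq(sim$genotypes[sim$metadata$population == "pop1", ])
  p2 <- allele_freq(sim$genotypes[sim$metadata$population == "pop2", ])
  expect_lt(mean(abs(p1 - p2)), 0.03)
})

test_that("realized missingness matches the requested rate", {
  sim <- simulate_island_genotypes(island_model_spec(
    n_pops = 1, n_per_pop = 60, n_snps = 500, fst = 0,
    geno_missing_rate = 0.3, seed = 5))
  expect_equal(mean(is.na(unclass(sim$genotypes))), 0.3, tolerance = 0.02 / 0.3)
})

test_that("multi-locus Weir-Cockerham estimates recover the simulated F", {
  sim <- simulate_island_genotypes(island_model_spec(
    n_pops = 2, n_per_pop = 200, n_snps = 5000, fst = 0.1, seed = 1))
  theta <- wc_fst(sim$genotypes, sim$metadata$population)
  expect_equal(theta, 0.1, tolerance = 0.02 / 0.1)
})

test_that("inject_relatives plants near-duplicates with the stated kernel", {
  sim <- simulate_island_genotypes(island_model_spec(
    n_pops = 1, n_per_pop = 6, n_snps = 1000, fst = 0, seed = 8))
  ids <- rownames(sim$genotypes)
  g0 <- inject_relatives(sim$genotypes, list(ids[1:2]), copy_error = 0)
  d0 <- ibs_distance_matrix(g0)
  expect_equal(d0[ids[1], ids[2]], 0)
  g1 <- inject_relatives(sim$genotypes, list(ids[1:2]), copy_error = 1, seed = 2)
  expect_gt(ibs_distance_matrix(g1)[ids[1], ids[2]], 0)
  # copy_error = 0.02: IBS distance equals the directly counted
  # perturbation distance on the realized pair
  g2 <- inject_relatives(sim$genotypes, list(ids[1:2]), copy_error = 0.02,
                         seed = 3)
  m <- unclass(g2)
  direct <- mean(abs(m[ids[1], ] - m[ids[2], ])) / 2
  expect_equal(ibs_distance_matrix(g2)[ids[1], ids[2]], direct)
  expect_equal(direct, 0.02 / 2 * 4 / 3, tolerance = 0.5)  # expected scale
  expect_error(inject_relatives(sim$genotypes,
                                list(ids[1:2], ids[2:3])), "overlapping")
})

test_that("read-assignment simulation follows its binomial contract", {
  spec <- hybrid_sim_spec(n_ind = 60, mean_reads = 5000, baseline_frac = 0.01,
                          hybrid_ids = "ind007", hybrid_frac = 0.2, seed = 6)
  tab <- simulate_read_assignments(spec)
  pct <- percent_alt_reference(tab)
  frac <- ifelse(pct$sample_id == "ind007", 0.2, 0.01)
  total <- pct$reads_ref_primary + pct$reads_ref_alt
  # individuals sit inside the 99% binomial interval of their parameter
  # (at worst the odd one of 60 strays, as the interval itself implies)
  lo <- stats::qbinom(0.005, total, frac)
  hi <- stats::qbinom(0.995, total, frac)
  inside <- pct$reads_ref_alt >= lo & pct$reads_ref_alt <= hi
  expect_gte(mean(inside), 0.95)
  expect_true(inside[pct$sample_id == "ind007"])
  expect_error(hybrid_sim_spec(10, mean_reads = 0), "positive")
  expect_error(hybrid_sim_spec(10, baseline_frac = 0.3, hybrid_frac = 0.2),
               "exceed")
})

test_that("grid simulation honours its degenerate and spatial contracts", {
  poly <- square_polygon()
  one <- simulate_grid_genotypes(grid_model_spec(
    poly, 1, n_per_deme = 4, n_snps = 30, seed = 2))
  # single deme: everyone shares one frequency vector
  expect_equal(nrow(one$true_freq), 1L)
  expect_equal(nrow(one$grid$demes), 1L)

  spec <- grid_model_spec(poly, 20, migration_field = 5,
                          within_deme_diversity = 2, n_per_deme = 2,
                          n_snps = 400, seed = 7)
  sim <- simulate_grid_genotypes(spec)
  expect_true(all(mgcv::in.out(
    as.matrix(rbind(poly, poly[1, ])),
    as.matrix(sim$grid$demes[, c("lon", "lat")]))))
  # dissimilarity grows with graph distance, faster under low migration
  slope_of <- function(m_rate, seed) {
    s <- simulate_grid_genotypes(grid_model_spec(
      poly, 20, migration_field = m_rate, within_deme_diversity = 2,
      n_per_deme = 2, n_snps = 400, seed = seed))
    f <- s$true_freq
    dd <- as.matrix(dist(f))^2 / ncol(f)
    gr <- igraph::graph_from_edgelist(
      cbind(s$grid$edges$from, s$grid$edges$to), directed = FALSE)
    hops <- igraph::distances(gr)
    ut <- upper.tri(dd)
    stats::coef(stats::lm(dd[ut] ~ hops[ut]))[2]
  }
  expect_gt(slope_of(0.2, 7), slope_of(20, 7))
  expect_gt(slope_of(20, 7), 0)
})

test_that("a low-m band raises cross-barrier dissimilarity at equal distance", {
  poly <- square_polygon(12, 4)
  barrier_f <- function(lon, lat) ifelse(lon > 4.2 & lon < 7.8, 0.1, 10)
  sim <- simulate_grid_genotypes(grid_model_spec(
    poly, 24, migration_field = barrier_f, within_deme_diversity = 5,
    n_per_deme = 2, n_snps = 600, seed = 2))
  f <- sim$true_freq
  dd <- as.matrix(dist(f))^2 / ncol(f)
  gr <- igraph::graph_from_edgelist(
    cbind(sim$grid$edges$from, sim$grid$edges$to), directed = FALSE)
  hops <- igraph::distances(gr)
  lon <- sim$grid$demes$lon
  side <- ifelse(lon < 4.2, "L", ifelse(lon > 7.8, "R", "B"))
  cross <- outer(side, side, function(a, b) (a == "L" & b == "R") |
                   (a == "R" & b == "L"))
  same <- outer(side, side, function(a, b) a == b & a != "B")
  ut <- upper.tri(dd)
  k <- 3
  expect_gt(mean(dd[ut & hops == k & cross]), mean(dd[ut & hops == k & same]))
})

test_that("RAD locus simulation respects SNP counts and divergence", {
  fixed <- simulate_rad_loci(n_loci = 8, locus_len = 110,
                             snps_per_locus = 5, n_ind = 10, seed = 3)
  expect_true(all(fixed$n_snps == 5L))
  expect_true(all(purrr::map_int(fixed$sequences, count_segregating_sites) == 5L))
  none <- simulate_rad_loci(n_loci = 4, locus_len = 110, snps_per_locus = 0,
                            outgroup_divergence = 0, n_ind = 5, seed = 4)
  expect_equal(clock_rate(none, snp_classes = 0)$rate, 0)
  # realized outgroup divergence near the per-site parameter
  div <- simulate_rad_loci(n_loci = 150, locus_len = 110, snps_per_locus = 0,
                           outgroup_divergence = 0.0159231, n_ind = 2, seed = 5)
  per_site <- purrr::map_dbl(seq_len(nrow(div)), function(k) {
    mean(purrr::map_dbl(div$sequences[[k]],
                        camelroutes:::seq_divergence, div$outgroup[k])) / 110
  })
  expect_equal(mean(per_site), 0.0159, tolerance = 0.15)
  expect_error(simulate_rad_loci(2, outgroup_divergence = 1.2), "\\[0, 1\\]")
})
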