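#' Specification of an island (Balding-Nichols) genotype simulation
#'
#' K discrete populations with a target fixation index under the
#' Balding-Nichols model: each SNP draws an ancestral frequency p uniformly
#' from `maf_range`, each population draws its own frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), and diploid genotypes are binomial draws
#' from the population frequency. F is the expected Wright FST of the
#' simulated populations.
#'
#' @param n_pops Number of populations (>= 1).
#' @param n_per_pop Individuals per population.
#' @param n_snps Number of SNPs.
#' @param fst Target differentiation F in `[0, 1)`; `fst = 0` gives
#'   identical frequencies in all populations (no Beta draw).
#' @param maf_range Ancestral-frequency bounds, a pair in `(0, 0.5]`.
#' @param ind_missing_rate Per-individual missing-call probability applied
#'   independently to every entry (default 0).
#' @param geno_missing_rate Per-entry missing-call probability (default 0).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return An `island_model_spec` list.
#' @export
island_model_spec <- function(n_pops, n_per_pop, n_snps, fst,
                              maf_range = c(0.05, 0.5),
                              ind_missing_rate = 0, geno_missing_rate = 0,
                              seed = 1L) {
  stopifnot(n_pops >= 1, n_per_pop >= 1, n_snps >= 1)
  if (fst < 0 || fst >= 1) rlang::abort("`fst` must be in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    rlang::abort("`maf_range` must be an increasing pair in (0, 0.5]")
  }
  for (r in c(ind_missing_rate, geno_missing_rate)) {
    if (r < 0 || r >= 1) rlang::abort("missing rates must be in [0, 1)")
  }
  structure(
    list(n_pops = as.integer(n_pops), n_per_pop = as.integer(n_per_pop),
         n_snps = as.integer(n_snps), fst = fst, maf_range = maf_range,
         ind_missing_rate = ind_missing_rate,
         geno_missing_rate = geno_missing_rate, seed = as.integer(seed)),
    class = "island_model_spec"
  )
}

# one global seed expands to per-component child seeds by fixed offsets
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

#' Simulate island-model genotypes
#'
#' @param spec An [island_model_spec()].
#' @return List with `genotypes` (a [geno_matrix()]), `metadata` (sample
#'   metadata tibble; populations are labelled `pop1..popK` and assigned
#'   alternating Africa/Asia continents for grouping convenience), `snps`
#'   (SNP table with synthetic scaffold/position/alleles) and `true_freq`
#'   (the per-population allele-frequency matrix actually used).
#' @examples
#' sim <- simulate_island_genotypes(island_model_spec(
#'   n_pops = 2, n_per_pop = 20, n_snps = 100, fst = 0.1, seed = 7))
#' sim$genotypes
#' @export
simulate_island_genotypes <- function(spec) {
  stopifnot(inherits(spec, "island_model_spec"))
  withr::local_seed(child_seed(spec$seed, 1))
  K <- spec$n_pops
  L <- spec$n_snps
  n <- spec$n_per_pop
  p0 <- stats::runif(L, spec$maf_range[1], spec$maf_range[2])
  F <- spec$fst
  freq <- matrix(0, K, L)
  if (F > 0) {
    a <- p0 * (1 - F) / F
    b <- (1 - p0) * (1 - F) / F
    for (k in seq_len(K)) freq[k, ] <- stats::rbeta(L, a, b)
  } else {
    freq <- matrix(rep(p0, each = K), K, L)
  }
  N <- K * n
  calls <- matrix(0L, N, L)
  pop <- rep(paste0("pop", seq_len(K)), each = n)
  for (k in seq_len(K)) {
    rows <- which(pop == paste0("pop", k))
    calls[rows, ] <- matrix(
      stats::rbinom(n * L, 2L, rep(freq[k, ], each = n)), n, L)
  }
  miss <- 1 - (1 - spec$geno_missing_rate) * (1 - spec$ind_missing_rate)
  if (miss > 0) {
    calls[stats::runif(N * L) < miss] <- NA_integer_
  }
  # orient every SNP to its realized minor allele so written PED/MAP files
  # read back to the identical matrix (alternate = minor is an invariant)
  obs_alleles <- 2 * colSums(!is.na(calls))
  realized <- colSums(calls, na.rm = TRUE) / pmax(obs_alleles, 1)
  flip <- realized > 0.5
  calls[, flip] <- 2L - calls[, flip]
  freq[, flip] <- 1 - freq[, flip]
  ids <- sprintf("%s_i%03d", pop, stats::ave(seq_len(N), pop, FUN = seq_along))
  g <- geno_matrix(calls, ids = ids, snp_ids = sprintf("snp%05d", seq_len(L)))
  continents <- rep(c("Africa", "Asia"), length.out = K)
  countries <- rep(c("EG", "SA", "KE", "PK", "LY", "IR", "TN", "IN"),
                   length.out = K)
  meta <- tibble::tibble(
    sample_id = ids,
    country = countries[match(pop, paste0("pop", seq_len(K)))],
    continent = continents[match(pop, paste0("pop", seq_len(K)))],
    population = pop,
    longitude = NA_real_, latitude = NA_real_
  )
  snps <- tibble::tibble(
    snp_id = colnames(g),
    scaffold = sprintf("scaf%03d", ((seq_len(L) - 1L) %% 20L) + 1L),
    position = as.integer(1000L + 500L * seq_len(L)),
    allele1 = ifelse(flip, "G", "A"), allele2 = ifelse(flip, "A", "G")
  )
  list(genotypes = g, metadata = meta, snps = snps, true_freq = freq)
}

#' Plant near-duplicate (related) individuals
#'
#' Each pair's second member becomes a copy of the first with every genotype
#' independently perturbed (replaced by one of the two other genotype
#' values, uniformly) with probability `copy_error`. Used to exercise
#' identity-by-state relatedness pruning.
#'
#' @param g A [geno_matrix()].
#' @param pairs List of length-2 character vectors of individual ids; an id
#'   may appear in at most one pair.
#' @param copy_error Per-genotype perturbation probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The modified [geno_matrix()].
#' @export
inject_relatives <- function(g, pairs, copy_error = 0, seed = 1L) {
  g <- as_geno_matrix(g)
  all_ids <- unlist(pairs)
  if (anyDuplicated(all_ids)) rlang::abort("overlapping pairs are not allowed")
  if (!all(all_ids %in% rownames(g))) {
    rlang::abort("all pair ids must exist in the genotype matrix")
  }
  withr::local_seed(as.integer(seed))
  m <- unclass(g)
  for (pr in pairs) {
    src <- m[pr[1], ]
    if (copy_error > 0) {
      flip <- !is.na(src) & stats::runif(length(src)) < copy_error
      if (any(flip)) {
        src[flip] <- vapply(src[flip], function(v) {
          sample(setdiff(0:2, v), 1L)
        }, integer(1))
      }
    }
    m[pr[2], ] <- src
  }
  geno_matrix(m)
}

#' Specification of a dual-reference read-assignment simulation
#'
#' Emulates competitive mapping of each individual's reads against the
#' dromedary (primary) and Bactrian camel (alternate) reference genomes:
#' total unambiguously mapped reads are Poisson, and the alternate-reference
#' count is binomial with a small baseline cross-mapping fraction, elevated
#' in designated hybrid individuals.
#'
#' @param n_ind Number of individuals.
#' @param mean_reads Mean total mapped reads per individual (Poisson mean).
#' @param baseline_frac Baseline alternate-reference fraction in `[0, 1)`.
#' @param hybrid_ids Character ids (among `ind001...`) of hybrid individuals.
#' @param hybrid_frac Elevated fraction for hybrids; must exceed
#'   `baseline_frac`.
#' @param seed Integer seed.
#' @return A `hybrid_sim_spec` list.
#' @export
hybrid_sim_spec <- function(n_ind, mean_reads = 1e5, baseline_frac = 0.01,
                            hybrid_ids = character(), hybrid_frac = 0.2,
                            seed = 1L) {
  stopifnot(n_ind >= 1)
  if (mean_reads <= 0) rlang::abort("`mean_reads` must be positive: no assignable reads otherwise")
  for (f in c(baseline_frac, hybrid_frac)) {
    if (f < 0 || f >= 1) rlang::abort("fractions must be in [0, 1)")
  }
  if (hybrid_frac <= baseline_frac) {
    rlang::abort("`hybrid_frac` must exceed `baseline_frac`")
  }
  structure(
    list(n_ind = as.integer(n_ind), mean_reads = mean_reads,
         baseline_frac = baseline_frac, hybrid_ids = as.character(hybrid_ids),
         hybrid_frac = hybrid_frac, seed = as.integer(seed)),
    class = "hybrid_sim_spec"
  )
}

#' Simulate a read-assignment table
#'
#' @param spec A [hybrid_sim_spec()].
#' @return Tibble with columns `sample_id`, `reads_ref_primary`,
#'   `reads_ref_alt`.
#' @export
simulate_read_assignments <- function(spec) {
  stopifnot(inherits(spec, "hybrid_sim_spec"))
  withr::local_seed(child_seed(spec$seed, 2))
  ids <- sprintf("ind%03d", seq_len(spec$n_ind))
  unknown <- setdiff(spec$hybrid_ids, ids)
  if (length(unknown)) {
    rlang::abort(paste0("hybrid ids not in cohort: ", paste(unknown, collapse = ", ")))
  }
  total <- stats::rpois(spec$n_ind, spec$mean_reads)
  frac <- ifelse(ids %in% spec$hybrid_ids, spec$hybrid_frac, spec$baseline_frac)
  alt <- stats::rbinom(spec$n_ind, total, frac)
  tibble::tibble(
    sample_id = ids,
    reads_ref_primary = total - alt,
    reads_ref_alt = alt
  )
}

#' Specification of a spatial (deme-grid) genotype simulation
#'
#' Stands in for spatially structured data under a stepping-stone model:
#' latent per-deme logit allele frequencies are drawn from a Gaussian Markov
#' random field whose precision is the migration-weighted graph Laplacian of
#' the deme grid plus a diagonal `1/q` term, so high migration couples
#' neighbouring demes tightly and low-`m` bands act as barriers.
#'
#' @param polygon Habitat polygon tibble (`lon`, `lat`), e.g. from
#'   [read_polygon()].
#' @param n_demes Approximate number of demes in the grid.
#' @param migration_field Either a single positive rate applied to every
#'   deme or a function `f(lon, lat)` returning per-deme positive rates.
#' @param within_deme_diversity Positive scalar q controlling independent
#'   per-deme frequency noise.
#' @param n_per_deme Individuals sampled per occupied deme.
#' @param n_snps Number of SNPs.
#' @param sample_demes Optional integer vector of deme indices to occupy
#'   (default: all demes).
#' @param seed Integer seed.
#' @return A `grid_model_spec` list.
#' @export
grid_model_spec <- function(polygon, n_demes, migration_field = 1,
                            within_deme_diversity = 1, n_per_deme = 2,
                            n_snps = 200, sample_demes = NULL, seed = 1L) {
  stopifnot(n_demes >= 1, n_per_deme >= 1, n_snps >= 1)
  if (within_deme_diversity <= 0) rlang::abort("`within_deme_diversity` must be > 0")
  if (is.numeric(migration_field) && any(migration_field <= 0)) {
    rlang::abort("all migration rates must be > 0")
  }
  structure(
    list(polygon = tibble::as_tibble(polygon), n_demes = as.integer(n_demes),
         migration_field = migration_field,
         within_deme_diversity = within_deme_diversity,
         n_per_deme = as.integer(n_per_deme), n_snps = as.integer(n_snps),
         sample_demes = sample_demes, seed = as.integer(seed)),
    class = "grid_model_spec"
  )
}

#' Simulate genotypes on a deme grid
#'
#' @param spec A [grid_model_spec()].
#' @return List with `genotypes`, `metadata` (with deme coordinates),
#'   `grid` (the [build_deme_grid()] result with the per-deme migration
#'   rates attached as `grid$demes$m`) and `true_freq` (deme x SNP).
#' @export
simulate_grid_genotypes <- function(spec) {
  stopifnot(inherits(spec, "grid_model_spec"))
  grid <- build_deme_grid(spec$polygon, spec$n_demes)
  D <- nrow(grid$demes)
  m <- if (is.function(spec$migration_field)) {
    spec$migration_field(grid$demes$lon, grid$demes$lat)
  } else {
    rep(spec$migration_field, length.out = D)
  }
  if (any(m <= 0)) rlang::abort("all migration rates must be > 0")
  grid$demes$m <- m
  q <- spec$within_deme_diversity

  withr::local_seed(child_seed(spec$seed, 3))
  # GMRF precision: migration-weighted Laplacian + I/q
  W <- matrix(0, D, D)
  if (nrow(grid$edges)) {
    w <- (m[grid$edges$from] + m[grid$edges$to]) / 2
    W[cbind(grid$edges$from, grid$edges$to)] <- w
    W[cbind(grid$edges$to, grid$edges$from)] <- w
  }
  Q <- diag(rowSums(W) + 1 / q, D) - W
  R <- chol(Q)  # Q = R'R, sample z = R^{-1} eps
  L <- spec$n_snps
  p0 <- stats::runif(L, 0.1, 0.5)
  eps <- matrix(stats::rnorm(D * L), D, L)
  z <- backsolve(R, eps)
  x <- sweep(z, 2, stats::qlogis(p0), "+")
  freq <- stats::plogis(x)

  occupied <- spec$sample_demes %||% seq_len(D)
  occupied <- sort(unique(as.integer(occupied)))
  if (any(occupied < 1 | occupied > D)) rlang::abort("sample_demes out of range")
  n <- spec$n_per_deme
  N <- length(occupied) * n
  calls <- matrix(0L, N, L)
  deme_of <- rep(occupied, each = n)
  for (i in seq_len(N)) {
    calls[i, ] <- stats::rbinom(L, 2L, freq[deme_of[i], ])
  }
  ids <- sprintf("d%03d_i%02d", deme_of,
                 stats::ave(seq_len(N), deme_of, FUN = seq_along))
  g <- geno_matrix(calls, ids = ids, snp_ids = sprintf("snp%05d", seq_len(L)))
  meta <- tibble::tibble(
    sample_id = ids,
    country = "XX", continent = NA_character_,
    population = sprintf("deme%03d", deme_of),
    longitude = grid$demes$lon[deme_of],
    latitude = grid$demes$lat[deme_of],
    deme = deme_of
  )
  list(genotypes = g, metadata = meta, grid = grid, true_freq = freq)
}

#' Simulate RAD-locus alignments with an outgroup
#'
#' Per locus: a random reference sequence, a chosen number of segregating
#' sites with two alleles among the ingroup, IUPAC-coded diploid consensus
#' sequences for each present individual, and one outgroup sequence
#' diverged from the reference at approximately
#' `outgroup_divergence * locus_len` sites.
#'
#' @param n_loci Number of loci.
#' @param locus_len Locus length in bases (the study's RAD reads are 110 bp).
#' @param snps_per_locus Integer range (length-2) or single value of
#'   segregating sites per locus.
#' @param presence Probability that an individual is present at a locus.
#' @param outgroup_divergence Expected per-site divergence of the outgroup
#'   in `[0, 1]`.
#' @param n_ind Number of ingroup individuals.
#' @param seed Integer seed.
#' @return A RAD locus set: tibble with columns `locus_id`, `length`,
#'   `n_snps`, `presence` (realized fraction present), `sequences`
#'   (list-column of named ingroup sequences) and `outgroup`.
#' @export
simulate_rad_loci <- function(n_loci, locus_len = 110L,
                              snps_per_locus = c(4L, 6L), presence = 0.9,
                              outgroup_divergence = 0.016, n_ind = 20L,
                              seed = 1L) {
  stopifnot(n_loci >= 1, locus_len >= 1, n_ind >= 1)
  if (outgroup_divergence < 0 || outgroup_divergence > 1) {
    rlang::abort("`outgroup_divergence` must be in [0, 1]")
  }
  rng <- range(as.integer(snps_per_locus))
  if (rng[1] < 0 || rng[2] > locus_len) {
    rlang::abort("`snps_per_locus` must lie within [0, locus_len]")
  }
  withr::local_seed(child_seed(seed, 4))
  bases <- c("A", "C", "G", "T")
  ids <- sprintf("ind%03d", seq_len(n_ind))
  rows <- purrr::map_dfr(seq_len(n_loci), function(l) {
    ref <- sample(bases, locus_len, replace = TRUE)
    s <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
    sites <- if (s > 0) sort(sample.int(locus_len, s)) else integer()
    present <- stats::runif(n_ind) < presence
    if (!any(present)) present[sample.int(n_ind, 1L)] <- TRUE
    seqs <- stats::setNames(rep(NA_character_, sum(present)), ids[present])
    # two alleles per segregating site; keep both observed among ingroup
    alt <- vapply(sites, function(j) sample(setdiff(bases, ref[j]), 1L),
                  character(1))
    n_pres <- sum(present)
    geno <- matrix(0L, n_pres, length(sites))
    for (jj in seq_along(sites)) {
      repeat {
        p <- stats::runif(1, 0.2, 0.8)
        gg <- stats::rbinom(n_pres, 2L, p)
        if (any(gg > 0L) && any(gg < 2L)) break  # keep the site segregating
      }
      geno[, jj] <- gg
    }
    for (i in seq_len(n_pres)) {
      sq <- ref
      for (jj in seq_along(sites)) {
        j <- sites[jj]
        sq[j] <- switch(as.character(geno[i, jj]),
                        "0" = ref[j],
                        "2" = alt[jj],
                        "1" = iupac_code(ref[j], alt[jj]))
      }
      seqs[i] <- paste(sq, collapse = "")
    }
    og <- ref
    n_div <- stats::rbinom(1L, locus_len, outgroup_divergence)
    if (n_div > 0) {
      dsites <- sample.int(locus_len, n_div)
      og[dsites] <- vapply(og[dsites],
                           function(b) sample(setdiff(bases, b), 1L),
                           character(1))
    }
    tibble::tibble(
      locus_id = sprintf("locus%04d", l),
      length = as.integer(locus_len),
      n_snps = length(sites),
      presence = n_pres / n_ind,
      sequences = list(seqs),
      outgroup = paste(og, collapse = "")
    )
  })
  rows
}
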