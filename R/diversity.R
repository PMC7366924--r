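#' Per-SNP expected and observed heterozygosity
#'
#' Ho is the fraction of heterozygotes among non-missing calls; He is the
#' unbiased gene diversity `(2n/(2n-1)) * (1 - p^2 - q^2)` with `n` the
#' number of non-missing diploid individuals. SNPs with fewer than two
#' non-missing calls get `NA` for both.
#'
#' @param g A [geno_matrix()], typically already subset to one group.
#' @return Tibble with columns `snp_id`, `n`, `ho`, `he`.
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 1L, 2L), 4, 1))
#' per_locus_heterozygosity(g)  # ho 0.5, he 8/7 * 0.5
#' @export
per_locus_heterozygosity <- function(g) {
  g <- as_geno_matrix(g)
  m <- unclass(g)
  n <- colSums(!is.na(m))
  ho <- colMeans(m == 1L, na.rm = TRUE)
  p <- allele_freq(g)
  he <- (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2)
  few <- n < 2
  ho[few] <- NA_real_
  he[few] <- NA_real_
  tibble::tibble(snp_id = colnames(m), n = as.integer(unname(n)),
                 ho = unname(ho), he = unname(he))
}

#' Per-SNP inbreeding coefficient
#'
#' `FIS = 1 - Ho / He`; SNPs with `He = 0` are undefined (`NA`) and excluded
#' from any group mean.
#'
#' @param het Tibble from [per_locus_heterozygosity()] (columns `ho`, `he`),
#'   or a [geno_matrix()] (computed internally).
#' @return The input tibble with an added `fis` column.
#' @export
inbreeding_coefficient <- function(het) {
  if (is_geno_matrix(het)) het <- per_locus_heterozygosity(het)
  dplyr::mutate(het, fis = ifelse(!is.na(.data$he) & .data$he > 0,
                                  1 - .data$ho / .data$he, NA_real_))
}

#' Rarefied allelic richness
#'
#' Hurlbert rarefaction of the allele count at each SNP to a common draw
#' size `g`: `AR = sum_a [1 - choose(N - N_a, g) / choose(N, g)]` over the
#' alleles present, where `N` is the group's non-missing allele count and
#' `N_a` the count of allele `a`. By default `g` is the smallest group's
#' non-missing allele count at that SNP (at least 2). Both `AR` (in [1, 2]
#' for biallelic data) and `AR - 1` are reported.
#'
#' @param g A [geno_matrix()].
#' @param groups Character/factor vector of group labels, one per
#'   individual.
#' @param rarefaction_size Optional fixed draw size (overrides the per-SNP
#'   minimum rule); must be >= 2.
#' @return Tibble with columns `group`, `snp_id`, `g_size`, `ar`,
#'   `ar_minus_1`.
#' @export
allelic_richness <- function(g, groups, rarefaction_size = NULL) {
  g <- as_geno_matrix(g)
  stopifnot(length(groups) == n_ind(g))
  groups <- as.character(groups)
  m <- unclass(g)
  lev <- sort(unique(groups))
  # per-group per-SNP allele counts
  counts <- purrr::map(lev, function(gr) {
    sub <- m[groups == gr, , drop = FALSE]
    n_alleles <- 2 * colSums(!is.na(sub))
    alt <- colSums(sub, na.rm = TRUE)
    list(n = n_alleles, alt = alt)
  })
  names(counts) <- lev
  g_size <- if (!is.null(rarefaction_size)) {
    rep(as.numeric(rarefaction_size), ncol(m))
  } else {
    do.call(pmin, purrr::map(counts, "n"))
  }
  if (any(g_size < 2)) {
    rlang::abort("rarefaction size below 2: a group has too few non-missing calls")
  }
  purrr::map_dfr(lev, function(gr) {
    N <- counts[[gr]]$n
    a2 <- counts[[gr]]$alt
    a1 <- N - a2
    ar <- numeric(ncol(m))
    for (j in seq_len(ncol(m))) {
      ks <- c(a1[j], a2[j])
      ks <- ks[ks > 0]
      ar[j] <- sum(1 - exp(lchoose(N[j] - ks, g_size[j]) - lchoose(N[j], g_size[j])))
    }
    tibble::tibble(group = gr, snp_id = colnames(m),
                   g_size = g_size, ar = ar, ar_minus_1 = ar - 1)
  })
}

#' Welch two-sample t test
#'
#' Thin wrapper over [stats::t.test()] (Welch variant) returning a tidy
#' one-row tibble; used to compare per-SNP diversity statistics between
#' groups.
#'
#' @param x,y Numeric vectors (NAs dropped).
#' @return Tibble with `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) rlang::abort("need >= 2 values per side")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    rlang::abort("both samples have zero variance")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_x = mean(x), mean_y = mean(y))
}

#' Group diversity summary
#'
#' Per-group mean and SD (over SNPs) of He, Ho and FIS, plus mean rarefied
#' allelic richness. Mean +/- SD summaries are over SNPs, matching how such
#' tables are reported for genome-wide panels.
#'
#' @param g A [geno_matrix()].
#' @param meta Sample metadata data frame (must cover all individuals).
#' @param group_by Metadata column to group by: `"country"`, `"continent"`
#'   or `"population"`. Use `NULL` for a single global group.
#' @return Tibble with one row per group: `group`, `n_ind`, `he_mean`,
#'   `he_sd`, `ho_mean`, `ho_sd`, `fis_mean`, `fis_sd`, `ar_mean`,
#'   `ar_minus_1_mean`.
#' @export
diversity_summary <- function(g, meta = NULL, group_by = NULL) {
  g <- as_geno_matrix(g)
  groups <- resolve_groups(g, meta, group_by)
  lev <- sort(unique(groups))
  per_group <- purrr::map_dfr(lev, function(gr) {
    sub <- g[groups == gr, , drop = FALSE]
    het <- inbreeding_coefficient(per_locus_heterozygosity(sub))
    tibble::tibble(
      group = gr, n_ind = nrow(sub),
      he_mean = mean(het$he, na.rm = TRUE), he_sd = stats::sd(het$he, na.rm = TRUE),
      ho_mean = mean(het$ho, na.rm = TRUE), ho_sd = stats::sd(het$ho, na.rm = TRUE),
      fis_mean = mean(het$fis, na.rm = TRUE), fis_sd = stats::sd(het$fis, na.rm = TRUE)
    )
  })
  ar <- NULL
  if (length(lev) > 1) {
    ar_ok <- tryCatch({
      ar_tab <- allelic_richness(g, groups)
      dplyr::summarise(dplyr::group_by(ar_tab, .data$group),
                       ar_mean = mean(.data$ar),
                       ar_minus_1_mean = mean(.data$ar_minus_1),
                       .groups = "drop")
    }, error = function(e) NULL)
    ar <- ar_ok
  }
  if (!is.null(ar)) per_group <- dplyr::left_join(per_group, ar, by = "group")
  per_group
}

# map a grouping request to one label per individual, aligned with g's rows
resolve_groups <- function(g, meta, group_by) {
  if (is.null(group_by)) return(rep("all", n_ind(g)))
  if (is.null(meta)) rlang::abort("`meta` is required when `group_by` is set")
  meta <- tibble::as_tibble(meta)
  idx <- match(rownames(g), meta$sample_id)
  if (anyNA(idx)) {
    rlang::abort(paste0("metadata missing for: ",
                        paste(rownames(g)[is.na(idx)], collapse = ", ")))
  }
  if (!group_by %in% names(meta)) {
    rlang::abort(paste0("no metadata column `", group_by, "`"))
  }
  as.character(meta[[group_by]][idx])
}

# Weir & Cockerham (1984) variance components, vectorized across loci.
# Returns a 3 x L matrix of rows (a, b, c); columns where the estimator is
# undefined are NA.
wc_components <- function(m, groups) {
  ok <- !is.na(m)
  mm <- m
  mm[!ok] <- 0L
  grp <- as.factor(groups)
  N <- rowsum(ok + 0, grp)          # pops x loci non-missing counts
  S <- rowsum(mm * ok, grp)         # sum of alt-allele counts
  H <- rowsum(((mm == 1L) & ok) + 0, grp) # heterozygote counts
  r <- colSums(N > 0)
  sum_n <- colSums(N)
  nbar <- ifelse(r > 0, sum_n / r, NA_real_)
  nc <- ifelse(r > 1, (sum_n - colSums(N^2) / sum_n) / (r - 1), NA_real_)
  p <- S / (2 * N)
  p[N == 0] <- 0
  pbar <- colSums(S) / (2 * sum_n)
  s2 <- colSums(N * sweep(p, 2, pbar, "-")^2) / ((r - 1) * nbar)
  hbar <- colSums(H) / sum_n
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  bad <- r < 2 | nbar <= 1 | !is.finite(nc) | nc == 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  rbind(a = a, b = b, c = cc)
}

#' Multi-locus Weir-Cockerham FST
#'
#' The 1984 theta estimator: per-locus variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals), combined as a ratio of sums over loci. Missing calls are
#' handled per SNP with pairwise-complete counts; loci where the estimator
#' is undefined (fewer than two populations with data) are skipped.
#'
#' @param g A [geno_matrix()].
#' @param groups Character vector of group labels, one per individual.
#' @return Single numeric theta (can be negative; reported as computed).
#' @export
wc_fst <- function(g, groups) {
  g <- as_geno_matrix(g)
  stopifnot(length(groups) == n_ind(g))
  comp <- wc_components(unclass(g), groups)
  keep <- colSums(is.finite(comp)) == 3
  tot <- sum(comp[, keep, drop = FALSE])
  if (tot == 0) return(0)
  sum(comp[1, keep]) / tot
}

#' Pairwise FST between groups with permutation significance
#'
#' For every pair of groups with at least `min_n` individuals each, the
#' multi-locus Weir-Cockerham theta, with significance from permuting
#' individuals between the two groups: `p = (1 + #\{perm >= obs\}) / (1 +
#' n_perm)`. Groups below the minimum are skipped and reported.
#'
#' @param g A [geno_matrix()].
#' @param meta Sample metadata (or `NULL` if `groups` given directly).
#' @param group_by Metadata column defining groups.
#' @param groups Optional explicit per-individual labels (overrides
#'   `meta`/`group_by`).
#' @param n_perm Number of permutations (0 to skip the test).
#' @param min_n Minimum individuals per group (the study used 3).
#' @param seed Integer seed for the permutations.
#' @return Tibble of class `fst_pairs`: `group1`, `group2`, `n1`, `n2`,
#'   `fst`, `p_value`, `n_perm`. Skipped pairs carry `NA` fst and the
#'   attribute `skipped` lists the undersized groups.
#' @export
pairwise_fst <- function(g, meta = NULL, group_by = "country", groups = NULL,
                         n_perm = 1000, min_n = 3, seed = 1L) {
  g <- as_geno_matrix(g)
  if (is.null(groups)) groups <- resolve_groups(g, meta, group_by)
  stopifnot(length(groups) == n_ind(g))
  withr::local_seed(as.integer(seed))
  lev <- sort(unique(groups))
  sizes <- table(groups)
  small <- names(sizes)[sizes < min_n]
  lev_ok <- setdiff(lev, small)
  if (length(small)) {
    rlang::warn(paste0("groups below the minimum of ", min_n,
                       " individuals skipped: ", paste(small, collapse = ", ")))
  }
  pairs <- utils::combn(lev_ok, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    rows <- groups %in% pr
    sub <- g[rows, , drop = FALSE]
    lab <- groups[rows]
    obs <- wc_fst(sub, lab)
    p <- NA_real_
    if (n_perm > 0) {
      ge <- 0L
      for (b in seq_len(n_perm)) {
        if (wc_fst(sub, sample(lab)) >= obs) ge <- ge + 1L
      }
      p <- (1 + ge) / (1 + n_perm)
    }
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   n1 = sum(lab == pr[1]), n2 = sum(lab == pr[2]),
                   fst = obs, p_value = p, n_perm = as.integer(n_perm))
  })
  attr(out, "skipped") <- small
  class(out) <- c("fst_pairs", class(out))
  out
}

# AMOVA sums of squared deviations via pairwise squared allele differences,
# vectorized across loci. Allele values are 0/1 indicators of the alternate
# allele; each diploid individual contributes two alleles. For a set of n
# alleles of which k are the alternate, sum_{i<j} d_ij^2 / n = k (n - k) / n.
amova_ssd <- function(m, pops) {
  ok <- !is.na(m)
  mm <- m
  mm[!ok] <- 0L
  # within individuals: a heterozygote's two alleles differ -> SSD 1/2
  ssd_wi <- sum(mm == 1L & ok) / 2
  grp <- as.factor(pops)
  N <- 2 * rowsum(ok + 0, grp)  # pops x loci allele counts
  K <- rowsum(mm * ok, grp)
  wp <- K * (N - K) / N
  wp[N == 0] <- 0
  ssd_wp <- sum(wp)
  n_tot <- colSums(N)
  k_tot <- colSums(K)
  tot <- k_tot * (n_tot - k_tot) / n_tot
  tot[n_tot == 0] <- 0
  c(total = sum(tot), within_pop = ssd_wp, within_ind = ssd_wi)
}

#' Hierarchical AMOVA on diploid genotypes
#'
#' Three-level analysis of molecular variance: among populations, among
#' individuals within populations, and within individuals, computed from
#' squared allele differences summed over loci. Variance components follow
#' the standard moment equations; percentages are components over their
#' total; significance by permuting individuals among populations.
#' Negative components are reported as computed, not truncated.
#'
#' @param g A [geno_matrix()].
#' @param populations Character vector of population labels per individual.
#' @param n_perm Permutations for the among-population component (0 skips).
#' @param seed Integer seed.
#' @return Object of class `amova_result`: list with `components` tibble
#'   (`level`, `df`, `ssd`, `sigma2`, `percent`, `p_value`) and call info.
#'   `tidy()` returns the components, `glance()` the percentages.
#' @export
amova <- function(g, populations, n_perm = 1000, seed = 1L) {
  g <- as_geno_matrix(g)
  stopifnot(length(populations) == n_ind(g))
  populations <- as.character(populations)
  if (length(unique(populations)) < 2) rlang::abort("need >= 2 populations")
  withr::local_seed(as.integer(seed))

  comp <- amova_components(g, populations)
  if (is.null(comp)) rlang::abort("degenerate data: total variance is zero")
  obs_sigma <- comp$sigma2
  p_vals <- rep(NA_real_, 3)
  if (n_perm > 0) {
    ge_a <- 0L
    for (b in seq_len(n_perm)) {
      perm <- amova_components(g, sample(populations))
      if (!is.null(perm) && perm$sigma2[1] >= obs_sigma[1]) ge_a <- ge_a + 1L
    }
    p_vals[1] <- (1 + ge_a) / (1 + n_perm)
  }
  components <- tibble::tibble(
    level = c("among_populations", "among_individuals_within_populations",
              "within_individuals"),
    df = comp$df, ssd = comp$ssd, sigma2 = comp$sigma2,
    percent = 100 * comp$sigma2 / sum(comp$sigma2),
    p_value = p_vals
  )
  structure(list(components = components, n_perm = n_perm),
            class = "amova_result")
}

# moment-equation variance components summed over loci
amova_components <- function(g, populations) {
  m <- unclass(g)
  s <- amova_ssd(m, populations)
  ssd_tot <- s[["total"]]
  ssd_wp <- s[["within_pop"]]
  ssd_wi <- s[["within_ind"]]
  N <- nrow(m)
  P <- length(unique(populations))
  ssd_ap <- ssd_tot - ssd_wp
  ssd_ai <- ssd_wp - ssd_wi
  df <- c(P - 1, N - P, N)
  if (any(df <= 0)) rlang::abort("AMOVA needs more individuals than populations")
  ms <- c(ssd_ap, ssd_ai, ssd_wi) / df
  # allele-count coefficient for the among-population expectation
  n_all <- 2 * as.numeric(table(populations))
  n_prime <- (sum(n_all) - sum(n_all^2) / sum(n_all)) / (P - 1)
  sigma_c <- ms[3]
  sigma_b <- (ms[2] - sigma_c) / 2
  sigma_a <- (ms[1] - ms[2]) / n_prime
  tot <- sigma_a + sigma_b + sigma_c
  if (tot == 0) return(NULL)
  list(df = df, ssd = unname(c(ssd_ap, ssd_ai, ssd_wi)),
       sigma2 = c(sigma_a, sigma_b, sigma_c))
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>\n")
  print(x$components)
  invisible(x)
}

#' @export
tidy.amova_result <- function(x, ...) x$components

#' @export
glance.amova_result <- function(x, ...) {
  tibble::tibble(
    percent_among_populations = x$components$percent[1],
    percent_among_individuals = x$components$percent[2],
    percent_within_individuals = x$components$percent[3],
    p_among_populations = x$components$p_value[1]
  )
}
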