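#' Quality-control filter parameters
#'
#' The PLINK-style filter cascade settings: individual missingness, minor
#' allele frequency, genotype (per-SNP) missingness, and the
#' identity-by-state distance cutoff for relatedness pruning. The defaults
#' are the study settings (`--mind 0.25 --maf 0.01 --geno 0.25`, IBS cutoff
#' 0.05).
#'
#' @param max_ind_missing Drop individuals with missing fraction strictly
#'   greater than this ("more than", PLINK `--mind` semantics).
#' @param min_maf Drop SNPs with minor allele frequency strictly below this
#'   (kept at equality).
#' @param max_geno_missing Drop SNPs with missing fraction strictly greater
#'   than this (PLINK `--geno` semantics).
#' @param ibs_cutoff Pairs of individuals with IBS distance strictly below
#'   this are treated as near-duplicates; one member of each is pruned.
#' @return A `filter_params` list.
#' @export
filter_params <- function(max_ind_missing = 0.25, min_maf = 0.01,
                          max_geno_missing = 0.25, ibs_cutoff = 0.05) {
  for (v in c(max_ind_missing, min_maf, max_geno_missing, ibs_cutoff)) {
    if (v < 0 || v > 1) rlang::abort("all filter parameters must be in [0, 1]")
  }
  structure(
    list(max_ind_missing = max_ind_missing, min_maf = min_maf,
         max_geno_missing = max_geno_missing, ibs_cutoff = ibs_cutoff),
    class = "filter_params"
  )
}

#' Individual-missingness filter
#'
#' Drops individuals whose fraction of missing calls exceeds the threshold
#' (strict inequality: exactly 25\% missing is kept at the default).
#'
#' @param g A [geno_matrix()].
#' @param max_ind_missing Threshold in `[0, 1]`.
#' @return Filtered [geno_matrix()] with attribute `removed` (character ids).
#' @export
filter_individual_missingness <- function(g, max_ind_missing = 0.25) {
  g <- as_geno_matrix(g)
  rate <- ind_missing_rate(g)
  drop <- rate > max_ind_missing
  if (all(drop)) rlang::abort("individual-missingness filter removed all individuals")
  out <- g[!drop, , drop = FALSE]
  attr(out, "removed") <- rownames(g)[drop]
  out
}

#' Minor-allele-frequency filter
#'
#' MAF is computed on non-missing calls; SNPs below the threshold are
#' dropped, SNPs exactly at it are kept. SNPs with zero non-missing calls
#' are dropped with a warning.
#'
#' @param g A [geno_matrix()].
#' @param min_maf Threshold in `[0, 1]`.
#' @return Filtered [geno_matrix()] with attribute `removed` (SNP ids).
#' @export
filter_maf <- function(g, min_maf = 0.01) {
  g <- as_geno_matrix(g)
  maf <- minor_allele_freq(g)
  empty <- is.nan(maf)
  if (any(empty)) {
    rlang::warn(sprintf("%d SNP(s) with zero non-missing calls dropped", sum(empty)))
  }
  drop <- empty | maf < min_maf
  out <- g[, !drop, drop = FALSE]
  attr(out, "removed") <- colnames(g)[drop]
  out
}

#' Genotype-missingness filter
#'
#' Mirror of [filter_individual_missingness()] applied to SNPs: drops SNPs
#' whose missing-call fraction exceeds the threshold (strict).
#'
#' @param g A [geno_matrix()].
#' @param max_geno_missing Threshold in `[0, 1]`.
#' @return Filtered [geno_matrix()] with attribute `removed` (SNP ids).
#' @export
filter_genotype_missingness <- function(g, max_geno_missing = 0.25) {
  g <- as_geno_matrix(g)
  rate <- snp_missing_rate(g)
  drop <- rate > max_geno_missing
  out <- g[, !drop, drop = FALSE]
  attr(out, "removed") <- colnames(g)[drop]
  out
}

#' Identity-by-state distance matrix
#'
#' For each pair of individuals, over pairwise-complete SNPs, the shared
#' allele fraction at a SNP is `(2 - |g_i - g_j|) / 2`; the IBS distance is
#' one minus its mean. Pairs with no overlapping SNPs get `NA` with a
#' warning.
#'
#' @param g A [geno_matrix()] with at least 2 individuals.
#' @return Symmetric numeric matrix with zero diagonal.
#' @examples
#' g <- geno_matrix(rbind(a = c(0L, 2L), b = c(1L, 1L)))
#' ibs_distance_matrix(g)["a", "b"]  # 0.5
#' @export
ibs_distance_matrix <- function(g) {
  g <- as_geno_matrix(g)
  if (nrow(g) < 2) rlang::abort("need at least 2 individuals")
  m <- unclass(g)
  obs <- !is.na(m)
  m0 <- m
  m0[!obs] <- 0L
  # sum over complete SNPs of |g_i - g_j| via the identity
  # |a-b| = a + b - 2*min(a,b); use indicator expansion over the 3 levels
  n_pairs_complete <- obs %*% t(obs)
  # sum |g_i - g_j| over complete SNPs: expand with indicators of levels
  I0 <- (m0 == 0L) & obs
  I1 <- (m0 == 1L) & obs
  I2 <- (m0 == 2L) & obs
  abs_sum <- (I0 %*% t(I1)) + (I1 %*% t(I0)) +
    (I1 %*% t(I2)) + (I2 %*% t(I1)) +
    2 * ((I0 %*% t(I2)) + (I2 %*% t(I0)))
  d <- abs_sum / (2 * n_pairs_complete)
  if (any(n_pairs_complete == 0 & upper.tri(n_pairs_complete))) {
    rlang::warn("some pairs share no non-missing SNPs; their distance is NA")
    d[n_pairs_complete == 0] <- NA_real_
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(g), rownames(g))
  d
}

#' Prune near-duplicate individuals
#'
#' Pairs with IBS distance strictly below the cutoff form a relatedness
#' graph; while any such pair remains, the member with the higher
#' missingness (ties: lexicographically later id) is removed.
#'
#' @param dist Symmetric IBS distance matrix, as from
#'   [ibs_distance_matrix()].
#' @param cutoff Distance cutoff; pairs below it are near-duplicates.
#' @param missingness Optional named numeric vector of per-individual
#'   missing fractions used to pick the removed member (default: all zero,
#'   so ties resolve lexicographically).
#' @return Character vector of removed individual ids.
#' @export
prune_relatives <- function(dist, cutoff = 0.05, missingness = NULL) {
  if (!isTRUE(all.equal(dist, t(dist), tolerance = 1e-8))) {
    rlang::abort("`dist` must be symmetric")
  }
  ids <- rownames(dist)
  if (is.null(missingness)) {
    missingness <- stats::setNames(rep(0, length(ids)), ids)
  }
  removed <- character()
  active <- ids
  repeat {
    d <- dist[active, active, drop = FALSE]
    hits <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
    if (!nrow(hits)) break
    # remove the worst member of the first remaining pair, then re-scan
    i <- active[hits[1, 1]]
    j <- active[hits[1, 2]]
    mi <- missingness[[i]] %||% 0
    mj <- missingness[[j]] %||% 0
    victim <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    removed <- c(removed, victim)
    active <- setdiff(active, victim)
    if (length(active) < 2) break
  }
  removed
}

#' Run the full QC filter cascade
#'
#' Applies, in the study's order: individual-missingness filter, minor
#' allele frequency filter, genotype-missingness filter, then
#' identity-by-state relatedness pruning. The report records every removal.
#'
#' @param g A [geno_matrix()].
#' @param params A [filter_params()].
#' @return An object of class `filter_cascade`: list with `genotypes`
#'   (the filtered [geno_matrix()]), `report` (tibble with one row per step:
#'   `step`, `axis`, `n_removed`, `removed` list-column) and `params`.
#'   `tidy()` returns the report, `glance()` before/after dimensions.
#' @export
run_filter_cascade <- function(g, params = filter_params()) {
  g <- as_geno_matrix(g)
  stopifnot(inherits(params, "filter_params"))
  n0 <- c(n_ind(g), n_snp(g))

  g1 <- filter_individual_missingness(g, params$max_ind_missing)
  rm_mind <- attr(g1, "removed")
  g2 <- filter_maf(g1, params$min_maf)
  rm_maf <- attr(g2, "removed")
  g3 <- filter_genotype_missingness(g2, params$max_geno_missing)
  rm_geno <- attr(g3, "removed")
  if (n_ind(g3) == 0 || n_snp(g3) == 0) {
    rlang::abort("filter cascade removed everything")
  }
  rm_ibs <- character()
  if (n_ind(g3) >= 2) {
    d <- ibs_distance_matrix(g3)
    rm_ibs <- prune_relatives(d, params$ibs_cutoff,
                              missingness = ind_missing_rate(g3))
  }
  g4 <- g3[setdiff(rownames(g3), rm_ibs), , drop = FALSE]
  if (n_ind(g4) == 0) rlang::abort("relatedness pruning removed everything")

  report <- tibble::tibble(
    step = c("individual_missingness", "minor_allele_frequency",
             "genotype_missingness", "relatedness_pruning"),
    axis = c("individuals", "snps", "snps", "individuals"),
    threshold = c(params$max_ind_missing, params$min_maf,
                  params$max_geno_missing, params$ibs_cutoff),
    n_removed = c(length(rm_mind), length(rm_maf), length(rm_geno),
                  length(rm_ibs)),
    removed = list(rm_mind, rm_maf, rm_geno, rm_ibs)
  )
  structure(
    list(genotypes = g4, report = report, params = params,
         dims_before = n0, dims_after = c(n_ind(g4), n_snp(g4))),
    class = "filter_cascade"
  )
}

#' @export
print.filter_cascade <- function(x, ...) {
  cat(sprintf("<filter_cascade> %d x %d -> %d x %d\n",
              x$dims_before[1], x$dims_before[2],
              x$dims_after[1], x$dims_after[2]))
  print(x$report[, c("step", "axis", "threshold", "n_removed")])
  invisible(x)
}

#' @export
tidy.filter_cascade <- function(x, ...) x$report

#' @export
glance.filter_cascade <- function(x, ...) {
  tibble::tibble(
    n_ind_before = x$dims_before[1], n_snp_before = x$dims_before[2],
    n_ind_after = x$dims_after[1], n_snp_after = x$dims_after[2],
    n_ind_removed = x$dims_before[1] - x$dims_after[1],
    n_snp_removed = x$dims_before[2] - x$dims_after[2]
  )
}
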