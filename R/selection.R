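#' Per-SNP per-group allele counts
#'
#' Counts of the reference and alternate alleles among non-missing calls in
#' each group; the input construction for the FST-outlier scan.
#'
#' @param g A [geno_matrix()].
#' @param groups Character vector of group labels (two or more groups, all
#'   non-empty).
#' @return List with `n` (groups x SNPs total allele counts), `alt`
#'   (alternate-allele counts) and `groups` (the group level names).
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 2L, 1L), 4, 1))
#' allele_counts_by_group(g, c("a", "a", "a", "b"))
#' @export
allele_counts_by_group <- function(g, groups) {
  g <- as_geno_matrix(g)
  stopifnot(length(groups) == n_ind(g))
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) < 2) rlang::abort("need at least two groups")
  if (any(table(factor(groups, lev)) == 0)) rlang::abort("empty group")
  m <- unclass(g)
  ok <- !is.na(m)
  mm <- m
  mm[!ok] <- 0L
  grp <- factor(groups, lev)
  n <- 2 * rowsum(ok + 0, grp)
  alt <- rowsum(mm * ok, grp)
  list(n = n, alt = alt, groups = lev, snp_ids = colnames(m))
}

# beta-binomial log-likelihood matrix for the F-model:
# alt_ij ~ BetaBin(n_ij, theta_ij p_i, theta_ij (1 - p_i)),
# theta_ij = 1/F_ij - 1, logit(F_ij) = alpha_i + beta_j
fmodel_loglik <- function(n, alt, p, alpha, beta) {
  L <- length(p)
  J <- length(beta)
  th <- exp(-outer(alpha, beta, "+"))  # L x J, theta = exp(-(alpha+beta))
  a <- th * p
  b <- th * (1 - p)
  altT <- t(alt)  # L x J
  nT <- t(n)
  ll <- lbeta(altT + a, nT - altT + b) - lbeta(a, b)
  rowSums(ll)  # per-locus log-likelihood summed over groups
}

#' Bayesian FST-outlier scan
#'
#' A logistic F-model scan for loci under selection between groups:
#' `logit(F_ij) = alpha_i + beta_j` with a locus effect `alpha_i` and a
#' group effect `beta_j`; group allele counts follow a beta-binomial
#' (multinomial-Dirichlet) likelihood given the locus's ancestral frequency
#' `p_i`. A reversible-jump MCMC toggles inclusion of each `alpha_i`, with
#' prior odds for neutrality, using the prior as the jump proposal so the
#' acceptance ratio reduces to the likelihood ratio times the prior
#' inclusion odds. The q-value of locus i is the mean posterior neutrality
#' probability over all loci with inclusion probability at least as large
#' as locus i's; outliers are loci with q-value below the FDR threshold.
#'
#' @param counts Allele counts from [allele_counts_by_group()].
#' @param prior_odds Prior odds for neutrality (the cited tool's default 10).
#' @param n_burnin Burn-in iterations.
#' @param n_sample Retained posterior samples.
#' @param thin Thinning interval between retained samples.
#' @param n_pilot,pilot_len Pilot runs used to tune proposal scales.
#' @param fdr FDR threshold for declaring outliers.
#' @param seed Integer seed.
#' @return Object of class `outlier_scan`: tibble `result` with per-SNP
#'   `snp_id`, `alpha_mean`, `prob_included`, `q_value`, `fst`, `outlier`;
#'   plus chain diagnostics. `tidy()` returns the per-SNP table.
#' @export
bayescan_fit <- function(counts, prior_odds = 10,
                         n_burnin = 2000, n_sample = 2000, thin = 5,
                         n_pilot = 5, pilot_len = 200,
                         fdr = 0.05, seed = 1L) {
  n <- counts$n
  alt <- counts$alt
  J <- nrow(n)
  L <- ncol(n)
  if (J < 2) rlang::abort("need at least two groups")
  withr::local_seed(as.integer(seed))
  pi_incl <- 1 / (1 + prior_odds)
  sd_alpha_prior <- 1     # N(0, 1) prior on included locus effects
  mu_beta <- -1           # N(-1, 1) prior on group effects
  sd_beta_prior <- 1

  # state
  p <- pmin(pmax((colSums(alt) + 1) / (colSums(n) + 2), 0.01), 0.99)
  alpha <- rep(0, L)
  delta <- rep(FALSE, L)
  beta <- rep(-1, J)
  scale_p <- rep(0.1, 1)
  scale_a <- 0.4
  scale_b <- 0.2

  ll <- fmodel_loglik(n, alt, p, alpha, beta)  # per locus

  update_p <- function() {
    prop <- p + stats::rnorm(L, 0, scale_p)
    okp <- prop > 1e-4 & prop < 1 - 1e-4
    prop[!okp] <- p[!okp]
    ll_new <- fmodel_loglik(n, alt, prop, alpha, beta)
    acc <- okp & (log(stats::runif(L)) < ll_new - ll)
    p[acc] <<- prop[acc]
    ll[acc] <<- ll_new[acc]
    mean(acc)
  }
  update_alpha <- function() {
    act <- which(delta)
    if (!length(act)) return(NA_real_)
    prop <- alpha
    prop[act] <- alpha[act] + stats::rnorm(length(act), 0, scale_a)
    ll_new <- fmodel_loglik(n, alt, p, prop, beta)
    lr <- ll_new - ll +
      stats::dnorm(prop, 0, sd_alpha_prior, log = TRUE) -
      stats::dnorm(alpha, 0, sd_alpha_prior, log = TRUE)
    acc <- rep(FALSE, L)
    acc[act] <- log(stats::runif(length(act))) < lr[act]
    alpha[acc] <<- prop[acc]
    ll[acc] <<- ll_new[acc]
    mean(acc[act])
  }
  update_beta <- function() {
    for (j in seq_len(J)) {
      prop <- beta
      prop[j] <- beta[j] + stats::rnorm(1, 0, scale_b)
      ll_new <- fmodel_loglik(n, alt, p, alpha, prop)
      lr <- sum(ll_new) - sum(ll) +
        stats::dnorm(prop[j], mu_beta, sd_beta_prior, log = TRUE) -
        stats::dnorm(beta[j], mu_beta, sd_beta_prior, log = TRUE)
      if (log(stats::runif(1)) < lr) {
        beta <<- prop
        ll <<- ll_new
      }
    }
  }
  update_delta <- function() {
    # reversible jump with the prior as proposal: acceptance is the
    # likelihood ratio times the prior inclusion odds
    prop_alpha <- alpha
    turn_on <- !delta
    prop_alpha[turn_on] <- stats::rnorm(sum(turn_on), 0, sd_alpha_prior)
    prop_alpha[!turn_on] <- 0
    ll_new <- fmodel_loglik(n, alt, p, prop_alpha, beta)
    log_odds <- ifelse(turn_on,
                       ll_new - ll + log(pi_incl) - log(1 - pi_incl),
                       ll_new - ll + log(1 - pi_incl) - log(pi_incl))
    acc <- log(stats::runif(L)) < log_odds
    alpha[acc] <<- prop_alpha[acc]
    delta[acc] <<- turn_on[acc]
    ll[acc] <<- ll_new[acc]
    mean(acc)
  }

  # pilot runs: adapt proposal scales toward mid-range acceptance
  for (pr in seq_len(n_pilot)) {
    acc_p <- acc_a <- c()
    for (it in seq_len(pilot_len)) {
      acc_p <- c(acc_p, update_p())
      acc_a <- c(acc_a, update_alpha())
      update_beta()
      update_delta()
    }
    ap <- mean(acc_p, na.rm = TRUE)
    if (is.finite(ap)) scale_p <- scale_p * ifelse(ap < 0.25, 0.7, ifelse(ap > 0.45, 1.4, 1))
    aa <- mean(acc_a, na.rm = TRUE)
    if (is.finite(aa)) scale_a <- scale_a * ifelse(aa < 0.25, 0.7, ifelse(aa > 0.45, 1.4, 1))
  }
  for (it in seq_len(n_burnin)) {
    update_p(); update_alpha(); update_beta(); update_delta()
  }
  alpha_sum <- rep(0, L)
  incl_sum <- rep(0, L)
  fst_sum <- rep(0, L)
  acc_trace <- numeric(n_sample)
  for (s in seq_len(n_sample)) {
    for (t in seq_len(thin)) {
      update_p(); update_alpha(); update_beta()
      acc_trace[s] <- update_delta()
    }
    alpha_sum <- alpha_sum + alpha
    incl_sum <- incl_sum + delta
    fst_sum <- fst_sum + rowMeans(stats::plogis(outer(alpha, beta, "+")))
  }
  prob <- incl_sum / n_sample
  # q-value: mean neutrality probability over all loci whose inclusion
  # probability is at least that of locus i (ties share the same q-value)
  qv <- vapply(prob, function(pi_) mean(1 - prob[prob >= pi_]), numeric(1))
  out <- tibble::tibble(
    snp_id = counts$snp_ids %||% paste0("snp", seq_len(L)),
    alpha_mean = alpha_sum / n_sample,
    prob_included = prob,
    q_value = qv,
    fst = fst_sum / n_sample,
    outlier = qv < fdr
  )
  mixing_warning <- all(abs(prob - pi_incl) < 0.02)
  if (mixing_warning) {
    rlang::warn("inclusion probabilities all near the prior: chain may not be mixing")
  }
  structure(
    list(result = out, fdr = fdr, prior_odds = prior_odds,
         beta_mean = beta, n_sample = n_sample,
         mixing_warning = mixing_warning),
    class = "outlier_scan"
  )
}

#' @export
print.outlier_scan <- function(x, ...) {
  cat(sprintf("<outlier_scan> %d loci, %d outliers at FDR %.2f\n",
              nrow(x$result), sum(x$result$outlier), x$fdr))
  invisible(x)
}

#' @export
tidy.outlier_scan <- function(x, ...) x$result

#' @export
glance.outlier_scan <- function(x, ...) {
  tibble::tibble(n_loci = nrow(x$result), n_outliers = sum(x$result$outlier),
                 fdr = x$fdr, prior_odds = x$prior_odds)
}

#' @param object An `outlier_scan` object.
#' @param ... Unused.
#' @rdname bayescan_fit
#' @export
autoplot.outlier_scan <- function(object, ...) {
  ggplot2::ggplot(object$result,
                  ggplot2::aes(x = log10(pmax(.data$q_value, 1e-4)),
                               y = .data$fst, colour = .data$outlier)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = log10(object$fdr), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log10 q-value", y = "FST") +
    ggplot2::theme_minimal()
}

#' Annotate outlier SNPs with flanking gene windows
#'
#' For each SNP, the closed window `[max(1, pos - flank), pos + flank]` on
#' its scaffold; a gene is reported when its interval overlaps the window by
#' at least one base. Genes on other scaffolds are never reported.
#'
#' @param snps Tibble with `snp_id`, `scaffold`, `position` (outlier SNPs;
#'   rows without a position are skipped with a warning).
#' @param genes Gene intervals from [read_gff_genes()] (`scaffold`, `start`,
#'   `end`, `gene`).
#' @param flank Window half-width in bases (the study used 200 kbp).
#' @return Tibble with `snp_id`, `scaffold`, `position`, `window_start`,
#'   `window_end`, `gene`, `gene_start`, `gene_end`; SNPs without any
#'   overlapping gene keep one row with `NA` gene.
#' @export
annotate_windows <- function(snps, genes, flank = 200000) {
  snps <- tibble::as_tibble(snps)
  genes <- tibble::as_tibble(genes)
  no_pos <- is.na(snps$position)
  if (any(no_pos)) {
    rlang::warn(paste0("skipping SNP(s) without position: ",
                       paste(snps$snp_id[no_pos], collapse = ", ")))
    snps <- snps[!no_pos, ]
  }
  wins <- dplyr::mutate(
    snps[, c("snp_id", "scaffold", "position")],
    window_start = pmax(1, .data$position - flank),
    window_end = .data$position + flank
  )
  hits <- dplyr::left_join(
    wins,
    dplyr::rename(genes, gene_start = "start", gene_end = "end"),
    by = dplyr::join_by("scaffold",
                        overlaps(x$window_start, x$window_end,
                                 y$gene_start, y$gene_end))
  )
  hits
}
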