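# shared fixtures, all generated in code

toy_geno <- function() {
  geno_matrix(rbind(
    a = c(0L, 1L, 2L, 0L),
    b = c(0L, 1L, 2L, 1L),
    c = c(2L, 1L, 0L, NA),
    d = c(1L, 1L, 1L, 2L)
  ), snp_ids = paste0("s", 1:4))
}

square_polygon <- function(w = 10, h = 5) {
  tibble::tibble(lon = c(0, w, w, 0), lat = c(0, 0, h, h))
}

# brute-force type-7 quantile via order statistics, kept independent of
# stats::quantile so the far-out rule has an external oracle
oracle_quartiles <- function(x) {
  x <- sort(x)
  n <- length(x)
  at <- function(p) {
    hh <- (n - 1) * p + 1
    lo <- floor(hh)
    hi <- ceiling(hh)
    x[lo] + (hh - lo) * (x[hi] - x[lo])
  }
  c(q1 = at(0.25), q3 = at(0.75))
}

# nested-ANOVA (mean-deviation) AMOVA sums of squares: an independent route
# to the same decomposition the package computes from pairwise distances
oracle_amova <- function(g, pops) {
  m <- unclass(g)
  N <- nrow(m)
  P <- length(unique(pops))
  ssd_ap <- ssd_ai <- ssd_wi <- 0
  for (j in seq_len(ncol(m))) {
    calls <- m[, j]
    ok <- !is.na(calls)
    # expand to allele indicators (0/1), two per individual
    al <- cbind(pmin(calls[ok], 1), pmax(calls[ok] - 1, 0))
    al[calls[ok] == 1L, ] <- matrix(rep(c(0, 1), each = sum(calls[ok] == 1L)),
                                    ncol = 2)
    pop <- pops[ok]
    grand <- mean(al)
    ind_mean <- rowMeans(al)
    pop_mean <- tapply(rep(ind_mean, 2) * 0 + c(al), rep(pop, 2), mean)
    # deviations: allele vs individual mean, individual vs pop mean,
    # pop vs grand mean (weighted by allele counts)
    ssd_wi <- ssd_wi + sum((al - ind_mean)^2)
    ssd_ai <- ssd_ai + 2 * sum((ind_mean - pop_mean[pop])^2)
    ssd_ap <- ssd_ap + sum(2 * table(pop)[names(pop_mean)] *
                             (pop_mean - grand)^2)
  }
  n_all <- 2 * as.numeric(table(pops))
  n_prime <- (sum(n_all) - sum(n_all^2) / sum(n_all)) / (P - 1)
  ms <- c(ssd_ap / (P - 1), ssd_ai / (N - P), ssd_wi / N)
  sigma_c <- ms[3]
  sigma_b <- (ms[2] - sigma_c) / 2
  sigma_a <- (ms[1] - ms[2]) / n_prime
  list(ssd = c(ssd_ap, ssd_ai, ssd_wi),
       sigma2 = c(sigma_a, sigma_b, sigma_c))
}
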