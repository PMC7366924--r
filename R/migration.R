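#' Build a triangular deme grid over a habitat polygon
#'
#' A triangular lattice spans the polygon's bounding box and is clipped to
#' the polygon; the lattice spacing is searched so the retained deme count
#' is within about 10 percent of `n_demes`. Edges connect lattice
#' neighbours; the retained graph must be connected.
#'
#' @param polygon Tibble with `lon`, `lat` ring vertices (e.g. from
#'   [read_polygon()]).
#' @param n_demes Target number of demes (>= 1).
#' @return Object of class `deme_grid`: list with `demes` tibble (`deme`,
#'   `lon`, `lat`), `edges` tibble (`from`, `to`) and `polygon`.
#' @export
build_deme_grid <- function(polygon, n_demes) {
  polygon <- tibble::as_tibble(polygon)
  stopifnot(n_demes >= 1)
  if (n_demes == 1) {
    ctr <- c(mean(polygon$lon), mean(polygon$lat))
    return(structure(
      list(demes = tibble::tibble(deme = 1L, lon = ctr[1], lat = ctr[2]),
           edges = tibble::tibble(from = integer(), to = integer()),
           polygon = polygon),
      class = "deme_grid"))
  }
  bb <- c(range(polygon$lon), range(polygon$lat))
  area_bb <- diff(bb[1:2]) * diff(bb[3:4])
  # rough polygon area for the initial spacing guess
  area_poly <- abs(.shoelace(polygon$lon, polygon$lat))
  h <- sqrt(2 * max(area_poly, area_bb / 10) / (sqrt(3) * n_demes))
  best <- NULL
  for (iter in 1:40) {
    cand <- .tri_lattice(bb, h)
    inside <- mgcv::in.out(as.matrix(rbind(polygon, polygon[1, ])),
                           as.matrix(cand))
    k <- sum(inside)
    if (is.null(best) || abs(k - n_demes) < abs(best$k - n_demes)) {
      best <- list(h = h, k = k)
    }
    if (abs(k - n_demes) <= max(1, 0.08 * n_demes)) break
    h <- h * sqrt(k / n_demes)
    if (!is.finite(h) || h <= 0) break
  }
  h <- best$h
  cand <- .tri_lattice(bb, h)
  inside <- mgcv::in.out(as.matrix(rbind(polygon, polygon[1, ])),
                         as.matrix(cand))
  pts <- cand[inside, , drop = FALSE]
  if (nrow(pts) < 1) rlang::abort("polygon too thin to hold any deme")
  # neighbours: lattice points within 1.1 spacing
  d2max <- (1.1 * h)^2
  n <- nrow(pts)
  edges <- list()
  for (i in seq_len(n - 1)) {
    d2 <- (pts[(i + 1):n, 1] - pts[i, 1])^2 + (pts[(i + 1):n, 2] - pts[i, 2])^2
    js <- which(d2 < d2max) + i
    if (length(js)) edges[[length(edges) + 1]] <- cbind(i, js)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else matrix(integer(), 0, 2)
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, n - igraph::vcount(gr)))
  if (igraph::components(gr)$no != 1) {
    rlang::abort("clipped deme grid is disconnected; adjust polygon or n_demes")
  }
  structure(
    list(demes = tibble::tibble(deme = seq_len(n), lon = pts[, 1], lat = pts[, 2]),
         edges = tibble::tibble(from = as.integer(edges[, 1]),
                                to = as.integer(edges[, 2])),
         polygon = polygon),
    class = "deme_grid"
  )
}

.tri_lattice <- function(bb, h) {
  xs <- seq(bb[1], bb[2], by = h)
  ys <- seq(bb[3], bb[4], by = h * sqrt(3) / 2)
  pts <- purrr::map_dfr(seq_along(ys), function(r) {
    off <- if (r %% 2 == 0) h / 2 else 0
    tibble::tibble(lon = xs + off, lat = ys[r])
  })
  as.data.frame(pts)
}

#' @export
print.deme_grid <- function(x, ...) {
  cat(sprintf("<deme_grid> %d demes, %d edges\n", nrow(x$demes), nrow(x$edges)))
  invisible(x)
}

#' Assign samples to their nearest deme
#'
#' Great-circle (haversine) distance from each sample's coordinates to each
#' deme centre.
#'
#' @param grid A [build_deme_grid()] result.
#' @param meta Metadata with `longitude` and `latitude` per sample.
#' @return Integer vector of deme indices, one per metadata row.
#' @export
assign_demes <- function(grid, meta) {
  meta <- tibble::as_tibble(meta)
  if (any(is.na(meta$longitude) | is.na(meta$latitude))) {
    rlang::abort("all samples need coordinates for deme assignment")
  }
  dm <- geosphere::distm(cbind(meta$longitude, meta$latitude),
                         cbind(grid$demes$lon, grid$demes$lat))
  apply(dm, 1, which.min)
}

#' Observed pairwise genetic dissimilarity
#'
#' `D_ij` is the mean over pairwise-complete SNPs of the squared genotype
#' difference `(g_i - g_j)^2` with genotypes in \{0, 1, 2\}; symmetric with
#' a zero diagonal. A pair with no overlapping SNPs is an error.
#'
#' @param g A [geno_matrix()] with >= 2 individuals.
#' @return Symmetric numeric matrix.
#' @examples
#' g <- geno_matrix(rbind(a = c(0L, 2L), b = c(2L, 0L), c = c(1L, 1L)))
#' observed_dissimilarity(g)["a", "b"]  # 4
#' @export
observed_dissimilarity <- function(g) {
  g <- as_geno_matrix(g)
  if (nrow(g) < 2) rlang::abort("need at least 2 individuals")
  m <- unclass(g)
  obs <- !is.na(m)
  m0 <- m
  m0[!obs] <- 0L
  n_complete <- obs %*% t(obs)
  if (any(n_complete == 0)) rlang::abort("a pair of individuals shares no non-missing SNPs")
  # sum over complete SNPs of (gi - gj)^2 = gi^2 + gj^2 - 2 gi gj,
  # restricted to mutually observed entries
  sq <- (m0^2) * obs
  cross <- m0 %*% t(m0)
  ssum <- sq %*% t(obs) + obs %*% t(sq) - 2 * cross
  d <- ssum / n_complete
  diag(d) <- 0
  dimnames(d) <- list(rownames(g), rownames(g))
  d
}

#' Expected dissimilarity under a migration surface
#'
#' Between-deme expectation is the effective resistance between demes on
#' the grid graph with edge conductance equal to the mean of the two
#' incident demes' migration rates, plus the mean of their within-deme
#' diversities; the within-deme expectation is the deme's own diversity.
#'
#' @param grid A [build_deme_grid()] result.
#' @param m Positive per-deme migration rates.
#' @param q Positive per-deme within-deme diversities (recycled if scalar).
#' @return Symmetric deme-by-deme matrix of expected dissimilarities.
#' @export
expected_dissimilarity <- function(grid, m, q) {
  D <- nrow(grid$demes)
  m <- rep(m, length.out = D)
  q <- rep(q, length.out = D)
  if (any(m <= 0) || any(q <= 0)) rlang::abort("m and q must be positive")
  R <- resistance_matrix(grid, m)
  E <- R + outer(q, q, "+") / 2
  diag(E) <- q
  E
}

# effective resistance via the Laplacian pseudo-inverse
resistance_matrix <- function(grid, m) {
  D <- nrow(grid$demes)
  if (D == 1) return(matrix(0, 1, 1))
  if (!nrow(grid$edges)) rlang::abort("disconnected grid: infinite resistance")
  W <- matrix(0, D, D)
  w <- (m[grid$edges$from] + m[grid$edges$to]) / 2
  W[cbind(grid$edges$from, grid$edges$to)] <- w
  W[cbind(grid$edges$to, grid$edges$from)] <- w
  L <- diag(rowSums(W)) - W
  Lp <- tryCatch(solve(L + 1 / D), error = function(e) {
    rlang::abort("disconnected grid: infinite resistance")
  })
  # pseudo-inverse identity: (L + J/D)^-1 = L^+ + J/D
  Lp <- Lp - 1 / D
  r <- outer(diag(Lp), diag(Lp), "+") - 2 * Lp
  r[r < 0] <- 0
  r
}

#' Fit an effective migration surface
#'
#' Random-walk Metropolis over per-deme log10 migration rates and log10
#' within-deme diversities, with a Gaussian smoothing prior on neighbouring
#' demes' log-rates and a Gaussian likelihood on the upper-triangle entries
#' of between-deme average observed dissimilarity versus the expectation of
#' [expected_dissimilarity()]. The residual standard deviation is profiled:
#' estimated from the fit residuals midway through burn-in and then held
#' fixed. Multiple chains are run and their per-deme posterior-mean
#' agreement reported. Posterior summaries of log10 m are normalized to a
#' zero mean over demes (zero is the overall mean migration rate).
#'
#' One iteration is a full sweep: a Metropolis update of every deme's
#' log-rate, of every occupied deme's diversity, and of the noise scale.
#'
#' @param d_obs Individual-by-individual dissimilarity from
#'   [observed_dissimilarity()].
#' @param grid A [build_deme_grid()] result.
#' @param sample_demes Integer vector assigning each row of `d_obs` to a
#'   deme (e.g. from [assign_demes()]).
#' @param n_iter Total sweeps per chain.
#' @param burn_in Sweeps discarded.
#' @param thin Keep every `thin`-th sweep.
#' @param proposal_scale Random-walk step (log10 units).
#' @param smooth_sd Smoothing prior SD on neighbouring log10-rate
#'   differences.
#' @param prior_sd Weak zero-mean prior SD on log10 rates.
#' @param n_chains Number of independent chains.
#' @param seed Integer seed.
#' @return Object of class `migration_surface`: `demes` tibble with
#'   posterior mean and 95% credible interval of normalized log10 m,
#'   `q_posterior`, `draws` (retained normalized draws, demes x draws),
#'   `diagnostics` (acceptance rates, between-chain correlation).
#' @export
fit_migration_surface <- function(d_obs, grid, sample_demes,
                                  n_iter = 2000, burn_in = n_iter %/% 2,
                                  thin = 2, proposal_scale = 0.15,
                                  smooth_sd = 0.35, prior_sd = 1,
                                  n_chains = 2, seed = 1L) {
  D <- nrow(grid$demes)
  stopifnot(length(sample_demes) == nrow(d_obs))
  occ <- sort(unique(sample_demes))
  if (length(occ) < 2) rlang::abort("need samples in at least 2 demes")

  # average observed dissimilarity between (and within) occupied demes
  grp <- factor(sample_demes, levels = occ)
  cnt <- table(grp)
  sums <- rowsum(t(rowsum(d_obs, grp)), grp)  # occupied x occupied sums
  npair <- outer(as.numeric(cnt), as.numeric(cnt))
  diag(npair) <- as.numeric(cnt) * (as.numeric(cnt) - 1)
  dbar <- sums / pmax(npair, 1)
  ut <- upper.tri(dbar)
  d_vec <- dbar[ut]

  nb <- cbind(grid$edges$from, grid$edges$to)

  # initial per-deme diversity: the observed within-deme average
  # dissimilarity estimates each occupied deme's baseline directly
  d_within <- diag(dbar)
  has_within <- as.numeric(cnt) >= 2 & d_within > 0
  lq0 <- rep(NA_real_, D)
  lq0[occ[has_within]] <- log10(d_within[has_within])
  fallback <- if (any(has_within)) mean(lq0, na.rm = TRUE) else log10(mean(d_vec) / 2 + 1e-6)
  lq0[is.na(lq0)] <- fallback

  # likelihood on the upper-triangle between-deme entries only; q enters
  # through the (q_a + q_b)/2 baseline of the between-deme expectation
  log_post <- function(lm, lq, lsig) {
    E <- expected_dissimilarity(grid, 10^lm, 10^lq)
    Eo <- E[occ, occ, drop = FALSE]
    resid <- d_vec - Eo[ut]
    ll <- sum(stats::dnorm(resid, 0, 10^lsig, log = TRUE))
    # the overall level of the field carries the (weakly identified) scale
    # and gets only a broad prior; shrinkage acts on deviations from it
    pr <- -sum((lm[nb[, 1]] - lm[nb[, 2]])^2) / (2 * smooth_sd^2) -
      sum((lm - mean(lm))^2) / (2 * prior_sd^2) -
      mean(lm)^2 / (2 * 9) -
      sum((lq[nb[, 1]] - lq[nb[, 2]])^2) / (2 * smooth_sd^2) -
      sum((lq - mean(lq))^2) / (2 * 4 * prior_sd^2) -
      mean(lq)^2 / (2 * 9)
    ll + pr
  }

  # the overall rate level is weakly identified but far from 0 in log10
  # units; a coarse 1-D scan finds the basin before the chains start
  level_resid <- function(level) {
    E <- expected_dissimilarity(grid, rep(10^level, D), 10^lq0)
    Eo <- E[occ, occ, drop = FALSE]
    stats::sd(d_vec - Eo[ut])
  }
  levels_try <- seq(-2, 4, by = 0.25)
  level0 <- levels_try[which.min(vapply(levels_try, level_resid, numeric(1)))]
  lsig0 <- log10(level_resid(level0) + 1e-9)

  # neighbourhoods for patch moves: a deme and its lattice neighbours
  nbr_list <- lapply(seq_len(D), function(d) {
    unique(c(d, nb[nb[, 1] == d, 2], nb[nb[, 2] == d, 1]))
  })

  # prior-preconditioned directions: eigenvectors of the smoothing-prior
  # precision, proposed with steps proportional to their prior sd, so the
  # weakly identified smooth field modes mix at their natural scale
  A <- matrix(0, D, D)
  if (nrow(nb)) {
    A[nb] <- 1
    A[nb[, 2:1, drop = FALSE]] <- 1
  }
  Lap <- diag(rowSums(A)) - A
  Qpr <- Lap / smooth_sd^2 + diag(D) / prior_sd^2
  ev <- eigen(Qpr, symmetric = TRUE)
  eig_V <- ev$vectors
  eig_sd <- 1 / sqrt(pmax(ev$values, 1e-12))

  run_chain <- function(chain_seed) {
    withr::local_seed(chain_seed)
    lm <- level0 + stats::rnorm(D, 0, 0.05)
    lq <- lq0 + stats::rnorm(D, 0, 0.02)
    lsig <- lsig0
    lp <- log_post(lm, lq, lsig)
    if (!is.finite(lp)) rlang::abort("non-finite posterior at initialization")
    # adaptive-Metropolis bookkeeping: the empirical covariance of the
    # field, accumulated during burn-in and frozen afterwards, drives
    # joint proposals that follow the posterior's correlated directions
    am_n <- 0L
    am_mean <- numeric(D)
    am_M2 <- matrix(0, D, D)
    am_chol <- NULL
    keep <- seq(burn_in + 1, n_iter, by = thin)
    draws_m <- matrix(0, D, length(keep))
    draws_q <- matrix(0, D, length(keep))
    k <- 0L
    n_acc <- 0L
    n_try <- 0L
    for (it in seq_len(n_iter)) {
      for (d in seq_len(D)) {
        prop <- lm
        prop[d] <- lm[d] + stats::rnorm(1, 0, proposal_scale)
        lp_new <- log_post(prop, lq, lsig)
        n_try <- n_try + 1L
        if (is.finite(lp_new) && log(stats::runif(1)) < lp_new - lp) {
          lm <- prop; lp <- lp_new; n_acc <- n_acc + 1L
        }
      }
      for (d in occ) {
        prop <- lq
        prop[d] <- lq[d] + stats::rnorm(1, 0, proposal_scale)
        lp_new <- log_post(lm, prop, lsig)
        n_try <- n_try + 1L
        if (is.finite(lp_new) && log(stats::runif(1)) < lp_new - lp) {
          lq <- prop; lp <- lp_new; n_acc <- n_acc + 1L
        }
      }
      # patch moves: shift a deme together with its neighbours so smooth
      # field modes mix much faster than under single-site updates alone
      for (pm in seq_len(max(1L, D %/% 3))) {
        patch <- nbr_list[[sample.int(D, 1L)]]
        prop <- lm
        prop[patch] <- lm[patch] + stats::rnorm(1, 0, proposal_scale)
        lp_new <- log_post(prop, lq, lsig)
        if (is.finite(lp_new) && log(stats::runif(1)) < lp_new - lp) {
          lm <- prop; lp <- lp_new
        }
      }
      # eigen moves along the prior's principal directions
      for (ek in seq_len(D)) {
        step <- stats::rnorm(1, 0, 0.6 * eig_sd[ek])
        prop <- lm + step * eig_V[, ek]
        lp_new <- log_post(prop, lq, lsig)
        if (is.finite(lp_new) && log(stats::runif(1)) < lp_new - lp) {
          lm <- prop; lp <- lp_new
        }
      }
      if (it <= burn_in && it > burn_in %/% 4) {
        am_n <- am_n + 1L
        delta <- lm - am_mean
        am_mean <- am_mean + delta / am_n
        am_M2 <- am_M2 + tcrossprod(delta, lm - am_mean)
      }
      if (it == burn_in && am_n > D) {
        S <- (2.38^2 / D) * (am_M2 / (am_n - 1) + diag(1e-8, D))
        am_chol <- tryCatch(chol(S), error = function(e) NULL)
      }
      if (!is.null(am_chol)) {
        for (jm in 1:4) {
          prop <- lm + drop(crossprod(am_chol, stats::rnorm(D)))
          lp_new <- log_post(prop, lq, lsig)
          if (is.finite(lp_new) && log(stats::runif(1)) < lp_new - lp) {
            lm <- prop; lp <- lp_new
          }
        }
      }
      # global shifts let the chain find the overall rate scale quickly;
      # the level itself is only weakly identified and is normalized out
      prop <- lm + stats::rnorm(1, 0, 2 * proposal_scale)
      lp_new <- log_post(prop, lq, lsig)
      if (is.finite(lp_new) && log(stats::runif(1)) < lp_new - lp) {
        lm <- prop; lp <- lp_new
      }
      prop <- lq + stats::rnorm(1, 0, proposal_scale)
      lp_new <- log_post(lm, prop, lsig)
      if (is.finite(lp_new) && log(stats::runif(1)) < lp_new - lp) {
        lq <- prop; lp <- lp_new
      }
      # the residual scale is estimated once (from the flat-field fit at
      # initialization) and held fixed: sampling it couples a slow global
      # mode into the field updates, and re-estimating it after the field
      # has absorbed noise understates it
      if (it > burn_in && (it - burn_in - 1) %% thin == 0) {
        k <- k + 1L
        if (k <= ncol(draws_m)) {
          draws_m[, k] <- lm - mean(lm)  # normalized: zero overall mean
          draws_q[, k] <- lq
        }
      }
    }
    list(draws_m = draws_m[, seq_len(k), drop = FALSE],
         draws_q = draws_q[, seq_len(k), drop = FALSE],
         acc_rate = n_acc / n_try)
  }

  chains <- purrr::map(seq_len(n_chains),
                       function(cc) run_chain(child_seed(seed, 200 + cc)))
  acc <- purrr::map_dbl(chains, "acc_rate")
  if (any(acc < 0.05 | acc > 0.8)) {
    rlang::warn(sprintf("MCMC acceptance rate outside [0.05, 0.8]: %s",
                        paste(sprintf("%.2f", acc), collapse = ", ")))
  }
  draws <- do.call(cbind, purrr::map(chains, "draws_m"))
  draws_q <- do.call(cbind, purrr::map(chains, "draws_q"))
  chain_means <- purrr::map(chains, function(ch) rowMeans(ch$draws_m))
  chain_cor <- if (n_chains >= 2) {
    stats::cor(chain_means[[1]], chain_means[[2]])
  } else NA_real_
  demes <- dplyr::mutate(
    grid$demes,
    log10_m_mean = rowMeans(draws),
    log10_m_lo = apply(draws, 1, stats::quantile, 0.025),
    log10_m_hi = apply(draws, 1, stats::quantile, 0.975),
    occupied = .data$deme %in% occ
  )
  structure(
    list(demes = demes, draws = draws, draws_q = draws_q, grid = grid,
         diagnostics = tibble::tibble(chain = seq_len(n_chains),
                                      acceptance = acc),
         chain_cor = chain_cor),
    class = "migration_surface"
  )
}

#' @export
print.migration_surface <- function(x, ...) {
  cat(sprintf(
    "<migration_surface> %d demes, %d draws; between-chain r = %s\n",
    nrow(x$demes), ncol(x$draws),
    ifelse(is.na(x$chain_cor), "NA", sprintf("%.3f", x$chain_cor))))
  invisible(x)
}

#' @export
tidy.migration_surface <- function(x, ...) x$demes

#' @export
glance.migration_surface <- function(x, ...) {
  tibble::tibble(n_demes = nrow(x$demes), n_draws = ncol(x$draws),
                 chain_cor = x$chain_cor,
                 mean_acceptance = mean(x$diagnostics$acceptance))
}

#' Classify demes into corridors, barriers and neutral
#'
#' A deme is a corridor when the posterior probability that its normalized
#' log10 migration rate exceeds 0 is at least `prob`; a barrier when the
#' probability of being below 0 is at least `prob`; otherwise neutral.
#'
#' @param surface A [fit_migration_surface()] result.
#' @param prob Posterior probability threshold (default 0.9).
#' @return The surface's `demes` tibble with added `p_above`, `p_below` and
#'   `class` columns.
#' @export
classify_surface <- function(surface, prob = 0.9) {
  stopifnot(inherits(surface, "migration_surface"))
  p_above <- rowMeans(surface$draws > 0)
  p_below <- rowMeans(surface$draws < 0)
  dplyr::mutate(
    surface$demes,
    p_above = p_above, p_below = p_below,
    class = dplyr::case_when(
      p_above >= prob ~ "corridor",
      p_below >= prob ~ "barrier",
      TRUE ~ "neutral"
    )
  )
}

#' @param object A `migration_surface` object.
#' @param samples Optional metadata with `longitude`/`latitude` to overlay
#'   sample diamonds sized by count per location.
#' @param ... Unused.
#' @rdname fit_migration_surface
#' @export
autoplot.migration_surface <- function(object, samples = NULL, ...) {
  p <- ggplot2::ggplot(object$demes,
                       ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$log10_m_mean), size = 4) +
    ggplot2::scale_colour_gradient2(low = "#8c510a", mid = "white",
                                    high = "#2166ac", midpoint = 0) +
    ggplot2::geom_path(data = dplyr::bind_rows(object$grid$polygon,
                                               object$grid$polygon[1, ]),
                       linetype = "dotted") +
    ggplot2::labs(colour = "log10(m)\n(0 = mean)") +
    ggplot2::theme_minimal()
  if (!is.null(samples)) {
    cnt <- dplyr::count(tibble::as_tibble(samples),
                        .data$longitude, .data$latitude)
    p <- p + ggplot2::geom_point(
      data = cnt,
      ggplot2::aes(x = .data$longitude, y = .data$latitude, size = .data$n),
      shape = 18)
  }
  p
}
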