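#' Principal component analysis of genotypes
#'
#' Genotypes are mean-imputed per SNP, column-centered (no variance
#' scaling) and decomposed with [stats::prcomp()]. Percent variance per
#' axis is its eigenvalue over the total, so the percentages over all axes
#' sum to 100. The sign of each axis is fixed by forcing its
#' largest-magnitude loading positive.
#'
#' @param g A [geno_matrix()] with at least 2 individuals.
#' @param n_axes Number of axes to retain in the scores (default 10).
#' @return Object of class `geno_pca`: list with `scores` tibble
#'   (`sample_id`, `PC1`, ...), `eigenvalues`, `percent_var`, `loadings`.
#'   `tidy()` returns the scores joined with percent variance in the axis
#'   names; `autoplot()` a PC1/PC2 scatter.
#' @export
pca_genotypes <- function(g, n_axes = 10) {
  g <- as_geno_matrix(g)
  if (nrow(g) < 2) rlang::abort("need at least 2 individuals")
  m <- unclass(g)
  mu <- colMeans(m, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(m))) {
    mj <- m[, j]
    mj[is.na(mj)] <- mu[j]
    m[, j] <- mj
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  if (all(eig < 1e-12)) {
    rlang::warn("constant genotype matrix: all eigenvalues are zero")
    pct <- rep(0, length(eig))
  } else {
    pct <- 100 * eig / sum(eig)
  }
  k <- min(n_axes, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (a in seq_len(k)) {  # deterministic sign: largest |loading| positive
    top <- which.max(abs(load[, a]))
    if (load[top, a] < 0) {
      load[, a] <- -load[, a]
      scores[, a] <- -scores[, a]
    }
  }
  structure(
    list(
      scores = dplyr::bind_cols(
        tibble::tibble(sample_id = rownames(g)),
        tibble::as_tibble(scores)),
      eigenvalues = eig, percent_var = pct, loadings = load
    ),
    class = "geno_pca"
  )
}

#' @export
print.geno_pca <- function(x, ...) {
  k <- min(3, length(x$percent_var))
  cat(sprintf("<geno_pca> %d individuals; first %d axes explain %.1f%% of variance\n",
              nrow(x$scores), k, sum(x$percent_var[seq_len(k)])))
  invisible(x)
}

#' @export
tidy.geno_pca <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 percent_var = x$percent_var)
}

#' @export
glance.geno_pca <- function(x, ...) {
  tibble::tibble(n_ind = nrow(x$scores),
                 percent_var_pc1_3 = sum(x$percent_var[seq_len(min(3, length(x$percent_var)))]))
}

#' @param object A `geno_pca` object.
#' @param meta Optional metadata to colour points by `colour_by`.
#' @param colour_by Metadata column name (default `"continent"`).
#' @param axes Which two PCs to plot.
#' @param ... Unused.
#' @rdname pca_genotypes
#' @export
autoplot.geno_pca <- function(object, meta = NULL, colour_by = "continent",
                              axes = c(1, 2), ...) {
  df <- object$scores
  xcol <- paste0("PC", axes[1])
  ycol <- paste0("PC", axes[2])
  if (!is.null(meta)) {
    df <- dplyr::left_join(df, tibble::as_tibble(meta), by = "sample_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]]))
  if (!is.null(meta) && colour_by %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]]))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(
    x = sprintf("%s (%.1f%%)", xcol, object$percent_var[axes[1]]),
    y = sprintf("%s (%.1f%%)", ycol, object$percent_var[axes[2]])) +
    ggplot2::theme_minimal()
}

# binomial ancestry log-likelihood over non-missing calls
admixture_loglik <- function(m, Q, F) {
  P <- Q %*% F
  eps <- 1e-9
  P <- pmin(pmax(P, eps), 1 - eps)
  sum((m * log(P) + (2 - m) * log(1 - P))[!is.na(m)])
}

#' Model-based ancestry estimation
#'
#' Maximizes the binomial ancestry likelihood
#' `sum_ij [ g_ij log(sum_k q_ik f_kj) + (2 - g_ij) log(sum_k q_ik (1 - f_kj)) ]`
#' over non-missing calls with an EM algorithm (multinomial responsibilities
#' over ancestry components for each of an individual's two allele draws).
#' Multiple random starts guard against local optima; the best likelihood is
#' kept.
#'
#' @param g A [geno_matrix()].
#' @param K Number of ancestral clusters (>= 1).
#' @param seed Integer seed (each start derives its own child seed).
#' @param tol Convergence: relative log-likelihood change below this stops.
#' @param max_iter Iteration cap; hitting it flags non-convergence.
#' @param n_starts Number of random restarts (default 3).
#' @return Object of class `admixture_fit`: list with `K`, `Q` (individuals
#'   x K ancestry fractions), `F` (K x SNPs cluster allele frequencies),
#'   `loglik`, `loglik_trace`, `converged`. `tidy()` returns Q in long
#'   format; `autoplot()` the stacked ancestry barplot.
#' @export
admixture_fit <- function(g, K, seed = 1L, tol = 1e-6, max_iter = 500,
                          n_starts = 3) {
  g <- as_geno_matrix(g)
  stopifnot(K >= 1)
  m <- unclass(g)
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- admixture_em_once(m, K, child_seed(seed, 100 + s), tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
    if (K == 1) break  # closed form, no multi-start needed
  }
  rownames(best$Q) <- rownames(m)
  colnames(best$Q) <- paste0("K", seq_len(K))
  colnames(best$F) <- colnames(m)
  structure(
    list(K = K, Q = best$Q, F = best$F, loglik = best$loglik,
         loglik_trace = best$trace, converged = best$converged),
    class = "admixture_fit"
  )
}

admixture_em_once <- function(m, K, seed, tol, max_iter) {
  withr::local_seed(seed)
  N <- nrow(m)
  L <- ncol(m)
  obs <- !is.na(m)
  g0 <- m
  g0[!obs] <- 0L
  n_obs <- rowSums(obs)
  if (any(n_obs == 0)) rlang::abort("individual with no non-missing calls")
  eps <- 1e-6
  if (K == 1) {
    F <- matrix(colSums(g0) / (2 * pmax(colSums(obs), 1)), 1, L)
    Q <- matrix(1, N, 1)
    ll <- admixture_loglik(m, Q, F)
    return(list(Q = Q, F = F, loglik = ll, trace = ll, converged = TRUE))
  }
  Q <- matrix(stats::rgamma(N * K, 1), N, K)
  Q <- Q / rowSums(Q)
  F <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)
  trace <- numeric()
  converged <- FALSE
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    Fc <- pmin(pmax(F, eps), 1 - eps)
    P <- Q %*% Fc            # N x L expected alt-allele frequency
    Pm <- 1 - P
    # responsibilities: alt-allele draws split as q_ik f_kj / P_ij,
    # ref-allele draws as q_ik (1 - f_kj) / (1 - P_ij)
    A_num <- matrix(0, N, K)  # per-individual expected alt assignments
    F_alt <- matrix(0, K, L)
    F_ref <- matrix(0, K, L)
    galt <- g0 * obs
    gref <- (2 - g0) * obs
    Walt <- galt / P          # N x L weights
    Wref <- gref / Pm
    for (k in seq_len(K)) {
      ak <- Q[, k] * t(Fc[k, ] * t(Walt))   # q_ik f_kj g_ij / P_ij
      rk <- Q[, k] * t((1 - Fc[k, ]) * t(Wref))
      F_alt[k, ] <- colSums(ak)
      F_ref[k, ] <- colSums(rk)
      A_num[, k] <- rowSums(ak) + rowSums(rk)
    }
    F <- F_alt / pmax(F_alt + F_ref, 1e-12)
    Q <- A_num / (2 * n_obs)
    Q <- pmax(Q, 1e-9)
    Q <- Q / rowSums(Q)
    ll <- admixture_loglik(m, Q, pmin(pmax(F, eps), 1 - eps))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(Q = Q, F = F, loglik = trace[length(trace)], trace = trace,
       converged = converged)
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> K = %d, log-likelihood %.2f%s\n",
              x$K, x$loglik,
              if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' @export
tidy.admixture_fit <- function(x, ...) {
  tibble::as_tibble(x$Q) |>
    dplyr::mutate(sample_id = rownames(x$Q), .before = 1) |>
    tidyr::pivot_longer(-"sample_id", names_to = "cluster",
                        values_to = "ancestry")
}

#' @export
glance.admixture_fit <- function(x, ...) {
  tibble::tibble(K = x$K, loglik = x$loglik, converged = x$converged,
                 n_iter = length(x$loglik_trace))
}

#' @param object An `admixture_fit` object.
#' @param meta Optional metadata; individuals are ordered by `order_by`.
#' @param order_by Metadata column for ordering the bars.
#' @param ... Unused.
#' @rdname admixture_fit
#' @export
autoplot.admixture_fit <- function(object, meta = NULL, order_by = "country",
                                   ...) {
  long <- tidy(object)
  if (!is.null(meta) && order_by %in% names(meta)) {
    ord <- tibble::as_tibble(meta) |>
      dplyr::arrange(.data[[order_by]]) |>
      dplyr::pull("sample_id")
    long$sample_id <- factor(long$sample_id, levels = ord)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$ancestry,
                                     fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "ancestry fraction",
                  title = sprintf("K = %d", object$K)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Cross-validated choice of the number of clusters
#'
#' Non-missing genotype entries are partitioned into `folds` folds; each
#' fold is masked in turn, the ancestry model refit on the remainder, and
#' the fold's error is the root mean squared deviation between the masked
#' genotypes and their model expectation `2 sum_k q_ik f_kj`. The best K
#' minimizes the mean error across folds.
#'
#' @param g A [geno_matrix()].
#' @param K_range Integer vector of K values to evaluate (the study scanned
#'   1 to 10).
#' @param folds Number of cross-validation folds (default 5, fivefold).
#' @param seed Integer seed (fold assignment and fits).
#' @param ... Passed to [admixture_fit()] (e.g. `tol`, `max_iter`,
#'   `n_starts`).
#' @return Object of class `admixture_cv`: list with `cv` tibble (`K`,
#'   `fold`, `cv_error`), `summary` (mean error per K) and `best_K`.
#' @export
admixture_cv <- function(g, K_range = 1:10, folds = 5, seed = 1L, ...) {
  g <- as_geno_matrix(g)
  m <- unclass(g)
  obs_idx <- which(!is.na(m))
  if (length(obs_idx) < folds) rlang::abort("not enough non-missing calls to mask")
  withr::local_seed(child_seed(seed, 7))
  fold_of <- sample(rep(seq_len(folds), length.out = length(obs_idx)))
  rows <- purrr::map_dfr(K_range, function(K) {
    errs <- purrr::map_dbl(seq_len(folds), function(f) {
      idx <- obs_idx[fold_of == f]
      if (!length(idx)) rlang::abort("a fold has zero entries")
      masked <- m
      masked[idx] <- NA_integer_
      fit <- admixture_fit(geno_matrix(masked), K, seed = child_seed(seed, K * 10 + f), ...)
      pred <- 2 * (fit$Q %*% fit$F)
      sqrt(mean((m[idx] - pred[idx])^2))
    })
    tibble::tibble(K = K, fold = seq_len(folds), cv_error = errs)
  })
  summary <- dplyr::summarise(dplyr::group_by(rows, .data$K),
                              mean_cv_error = mean(.data$cv_error),
                              .groups = "drop")
  best <- summary$K[which.min(summary$mean_cv_error)]
  structure(list(cv = rows, summary = summary, best_K = best),
            class = "admixture_cv")
}

#' @export
print.admixture_cv <- function(x, ...) {
  cat(sprintf("<admixture_cv> best K = %d\n", x$best_K))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.admixture_cv <- function(x, ...) x$cv

#' @export
glance.admixture_cv <- function(x, ...) {
  tibble::tibble(best_K = x$best_K,
                 min_cv_error = min(x$summary$mean_cv_error))
}

#' @param object An `admixture_cv` object.
#' @param ... Unused.
#' @rdname admixture_cv
#' @export
autoplot.admixture_cv <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$K, y = .data$mean_cv_error)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_K, linetype = "dotted") +
    ggplot2::labs(y = "cross-validation error") +
    ggplot2::theme_minimal()
}

#' Allele-sharing distance matrix
#'
#' The same identity-by-state kernel as [ibs_distance_matrix()], exposed for
#' export to external phylogenetic-network tools (square PHYLIP-style text
#' via [write_phylip_distance()]).
#'
#' @param g A [geno_matrix()].
#' @return Symmetric numeric matrix.
#' @export
allele_sharing_distance <- function(g) {
  ibs_distance_matrix(g)
}
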