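#' Diploid biallelic genotype matrix
#'
#' The central container of the pipeline: an individuals-by-SNPs integer
#' matrix of alternate-allele counts in \{0, 1, 2\}, with `NA` for missing
#' calls. Row names are individual ids, column names SNP ids; both are
#' required and must be unique.
#'
#' @param calls Integer matrix (individuals x SNPs) with values 0, 1, 2 or NA.
#' @param ids Optional character vector of individual ids (defaults to
#'   existing row names).
#' @param snp_ids Optional character vector of SNP ids (defaults to existing
#'   column names).
#'
#' @return An object of class `geno_matrix` (an integer matrix underneath).
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2),
#'                  ids = c("a", "b"), snp_ids = c("s1", "s2"))
#' n_ind(g)
#' @export
geno_matrix <- function(calls, ids = rownames(calls), snp_ids = colnames(calls)) {
  if (!is.matrix(calls)) {
    rlang::abort("`calls` must be a matrix.")
  }
  storage.mode(calls) <- "integer"
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    rlang::abort("genotype calls must be 0, 1, 2 or NA")
  }
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(calls)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(calls)))
  ids <- as.character(ids)
  snp_ids <- as.character(snp_ids)
  if (length(ids) != nrow(calls) || length(snp_ids) != ncol(calls)) {
    rlang::abort("id lengths must match matrix dimensions")
  }
  if (anyDuplicated(ids)) rlang::abort("individual ids must be unique")
  if (anyDuplicated(snp_ids)) rlang::abort("SNP ids must be unique")
  dimnames(calls) <- list(ids, snp_ids)
  class(calls) <- c("geno_matrix", class(calls))
  calls
}

#' @rdname geno_matrix
#' @param x Object to coerce or test.
#' @export
as_geno_matrix <- function(x) {
  if (is_geno_matrix(x)) return(x)
  geno_matrix(as.matrix(x))
}

#' @rdname geno_matrix
#' @export
is_geno_matrix <- function(x) inherits(x, "geno_matrix")

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d individuals x %d SNPs (%.1f%% missing)\n",
    nrow(x), ncol(x), 100 * mean(is.na(x))
  ))
  invisible(x)
}

# subsetting keeps the class and always returns a matrix
#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  class(out) <- c("geno_matrix", "matrix", "array")
  out
}

#' Dimensions and missingness helpers
#'
#' @param g A [geno_matrix()].
#' @return `n_ind()`/`n_snp()` return counts; `ind_missing_rate()` and
#'   `snp_missing_rate()` named numeric vectors of per-individual /
#'   per-SNP missing-call fractions; `allele_freq()` the per-SNP
#'   alternate-allele frequency among non-missing calls.
#' @export
n_ind <- function(g) nrow(g)

#' @rdname n_ind
#' @export
n_snp <- function(g) ncol(g)

#' @rdname n_ind
#' @export
ind_missing_rate <- function(g) rowMeans(is.na(unclass(g)))

#' @rdname n_ind
#' @export
snp_missing_rate <- function(g) colMeans(is.na(unclass(g)))

#' @rdname n_ind
#' @export
allele_freq <- function(g) {
  m <- unclass(g)
  colSums(m, na.rm = TRUE) / (2 * colSums(!is.na(m)))
}

#' Minor allele frequency per SNP
#'
#' Computed on non-missing calls only; SNPs with zero non-missing calls get
#' `NaN`.
#'
#' @param g A [geno_matrix()].
#' @return Named numeric vector in `[0, 0.5]`.
#' @export
minor_allele_freq <- function(g) {
  p <- allele_freq(g)
  pmin(p, 1 - p)
}
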