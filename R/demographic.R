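#' Select RAD loci for Extended Bayesian Skyline analysis
#'
#' A uniform random sample without replacement of `n` loci among those with
#' a segregating-site count in `[min_snps, max_snps]` and at least
#' `min_presence` of the individuals present (the study's rule: 4-6 SNPs
#' across at least 75 percent of individuals, 50 loci per run).
#'
#' @param loci RAD locus set tibble (e.g. from [simulate_rad_loci()] or
#'   [read_rad_fasta()]).
#' @param min_snps,max_snps Inclusive segregating-site bounds.
#' @param min_presence Minimum fraction of individuals present.
#' @param n Number of loci to draw.
#' @param seed Integer seed.
#' @return The selected subset of `loci` (same columns).
#' @export
select_ebsp_loci <- function(loci, min_snps = 4, max_snps = 6,
                             min_presence = 0.75, n = 50, seed = 1L) {
  loci <- tibble::as_tibble(loci)
  if (!nrow(loci)) rlang::abort("empty candidate locus pool")
  eligible <- loci$n_snps >= min_snps & loci$n_snps <= max_snps &
    (is.na(loci$presence) | loci$presence >= min_presence)
  pool <- loci[eligible, ]
  if (nrow(pool) < n) {
    rlang::abort(sprintf(
      "only %d loci are eligible (need %d): %d-%d SNPs at presence >= %.2f",
      nrow(pool), n, min_snps, max_snps, min_presence))
  }
  withr::local_seed(as.integer(seed))
  pool[sort(sample.int(nrow(pool), n)), ]
}

#' Calibrate a locus-specific clock rate from outgroup divergence
#'
#' Per locus, the mean count of differences between each ingroup sequence
#' and the outgroup, divided by the locus length, gives a per-site
#' divergence; loci are grouped by their segregating-site count (SNP
#' class), per-class means are taken, and the rate is the class-average
#' divergence divided by the split time and multiplied by the generation
#' time. IUPAC heterozygote positions count as half a difference when one
#' of their two alleles matches the outgroup base. The divergence is not
#' halved between the two lineages; the calibration divides by the split
#' time alone.
#'
#' @param loci RAD locus set tibble with ingroup `sequences` and an
#'   `outgroup` sequence per locus.
#' @param split_time Split time between ingroup and outgroup in years
#'   (default 4.4 million, the dromedary/Bactrian camel split).
#' @param generation_time Generation time in years (default 5).
#' @param snp_classes Classes to average over (default 4:6 segregating
#'   sites); loci outside these classes are ignored, empty classes skipped
#'   with a warning.
#' @return Object of class `clock_calibration`: list with `rate`
#'   (substitutions per site per generation), `class_divergence` tibble
#'   (`n_snps`, `n_loci`, `mean_divergence`), `mean_divergence` (the class
#'   average), `split_time`, `generation_time`.
#' @examples
#' calibrate_clock(0.0159231, 4.4e6, 5)  # 1.80944e-08
#' @export
clock_rate <- function(loci, split_time = 4.4e6, generation_time = 5,
                       snp_classes = 4:6) {
  loci <- tibble::as_tibble(loci)
  if (any(is.na(loci$outgroup) | !nzchar(loci$outgroup))) {
    rlang::abort("every locus needs an outgroup sequence")
  }
  if (any(loci$length == 0)) rlang::abort("zero-length locus")
  per_locus <- purrr::map_dbl(seq_len(nrow(loci)), function(k) {
    seqs <- loci$sequences[[k]]
    og <- loci$outgroup[k]
    diffs <- purrr::map_dbl(seqs, seq_divergence, og)
    mean(diffs) / loci$length[k]
  })
  loci$per_site_divergence <- per_locus
  present <- intersect(snp_classes, unique(loci$n_snps))
  missing_classes <- setdiff(snp_classes, present)
  if (length(missing_classes)) {
    rlang::warn(paste0("empty SNP class(es) skipped: ",
                       paste(missing_classes, collapse = ", ")))
  }
  if (!length(present)) rlang::abort("no locus falls in any requested SNP class")
  cls <- loci[loci$n_snps %in% present, ] |>
    dplyr::group_by(n_snps = .data$n_snps) |>
    dplyr::summarise(n_loci = dplyr::n(),
                     mean_divergence = mean(.data$per_site_divergence),
                     .groups = "drop")
  d <- mean(cls$mean_divergence)
  structure(
    list(rate = calibrate_clock(d, split_time, generation_time),
         class_divergence = cls, mean_divergence = d,
         split_time = split_time, generation_time = generation_time),
    class = "clock_calibration"
  )
}

#' @rdname clock_rate
#' @param mean_divergence Class-average per-site divergence.
#' @export
calibrate_clock <- function(mean_divergence, split_time = 4.4e6,
                            generation_time = 5) {
  if (mean_divergence < 0) rlang::abort("divergence must be >= 0")
  mean_divergence / split_time * generation_time
}

# count differences between an IUPAC-coded sequence and a plain outgroup
# sequence; a heterozygote with one matching allele counts 1/2
seq_divergence <- function(seq, outgroup) {
  a <- strsplit(toupper(seq), "")[[1]]
  b <- strsplit(toupper(outgroup), "")[[1]]
  if (length(a) != length(b)) rlang::abort("sequence length mismatch with outgroup")
  amb <- iupac_alleles()
  total <- 0
  for (j in seq_along(a)) {
    if (a[j] == "N" || b[j] == "N" || a[j] == "-" || b[j] == "-") next
    alleles <- amb[[a[j]]]
    if (is.null(alleles)) rlang::abort(paste0("unknown base code: ", a[j]))
    total <- total + mean(alleles != b[j])
  }
  total
}

#' @export
print.clock_calibration <- function(x, ...) {
  cat(sprintf("<clock_calibration> rate %.6e subst/site/generation (divergence %.6g, T %.3g y, g %.3g y)\n",
              x$rate, x$mean_divergence, x$split_time, x$generation_time))
  invisible(x)
}

#' @export
tidy.clock_calibration <- function(x, ...) x$class_divergence

#' @export
glance.clock_calibration <- function(x, ...) {
  tibble::tibble(rate = x$rate, mean_divergence = x$mean_divergence,
                 split_time = x$split_time, generation_time = x$generation_time)
}

#' Export loci as NEXUS alignments with a calibration manifest
#'
#' One NEXUS file per locus (DATA block with ntax, nchar, datatype=dna,
#' missing/gap codes, written via \pkg{ape}) plus a TSV manifest recording
#' per-locus metadata and the calibrated clock rate.
#'
#' @param loci Selected RAD locus set.
#' @param dir Output directory.
#' @param calibration Optional [clock_rate()] result recorded in the
#'   manifest.
#' @param include_outgroup Include the outgroup sequence in each alignment
#'   (default TRUE).
#' @param missing_as_gaps If TRUE, absent individuals are written as
#'   all-missing rows; default FALSE omits them.
#' @param all_ids Character vector of the full cohort (needed when
#'   `missing_as_gaps = TRUE`).
#' @return Invisibly, a list with `files` and the `manifest` tibble (also
#'   written to `manifest.tsv` in `dir`).
#' @export
export_nexus <- function(loci, dir, calibration = NULL,
                         include_outgroup = TRUE, missing_as_gaps = FALSE,
                         all_ids = NULL) {
  loci <- tibble::as_tibble(loci)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- purrr::map_chr(seq_len(nrow(loci)), function(k) {
    seqs <- loci$sequences[[k]]
    if (length(unique(nchar(seqs))) != 1L ||
        nchar(seqs[1]) != loci$length[k]) {
      rlang::abort(paste0("sequence-length mismatch in ", loci$locus_id[k]))
    }
    if (missing_as_gaps) {
      if (is.null(all_ids)) rlang::abort("`all_ids` needed with missing_as_gaps")
      absent <- setdiff(all_ids, names(seqs))
      if (length(absent)) {
        blanks <- stats::setNames(
          rep(strrep("?", loci$length[k]), length(absent)), absent)
        seqs <- c(seqs, blanks)
      }
    }
    if (include_outgroup) {
      seqs <- c(seqs, stats::setNames(loci$outgroup[k], "outgroup"))
    }
    path <- file.path(dir, paste0(loci$locus_id[k], ".nex"))
    ape::write.nexus.data(strsplit(tolower(seqs), ""), path,
                          format = "dna", interleaved = FALSE,
                          missing = "?", gap = "-")
    path
  })
  manifest <- tibble::tibble(
    locus_id = loci$locus_id, file = basename(files),
    length = loci$length, n_snps = loci$n_snps, presence = loci$presence,
    clock_rate = if (!is.null(calibration)) calibration$rate else NA_real_
  )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(list(files = files, manifest = manifest))
}
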