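#' Read PLINK text PED/MAP genotypes
#'
#' Reads the PLINK text dialect: the MAP file has columns
#' chromosome/scaffold, SNP id, genetic distance, 1-based position; the PED
#' file has six leading columns (family, individual, father, mother, sex,
#' phenotype) followed by two allele columns per SNP. An allele pair
#' containing the code `0` is a missing call. The alternate allele of each
#' SNP is defined as the minor allele computed on load (ties broken towards
#' the lexicographically greater allele) and recorded in the returned SNP
#' table, so all downstream statistics are invariant to how the input file
#' happened to orient its alleles.
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @return A list with elements `genotypes` (a [geno_matrix()]) and
#'   `snps` (a tibble: `snp_id`, `scaffold`, `position`, `allele1` the
#'   major/reference allele, `allele2` the minor/alternate allele counted in
#'   the genotype matrix).
#' @examples
#' sim <- simulate_island_genotypes(island_model_spec(
#'   n_pops = 2, n_per_pop = 3, n_snps = 4, fst = 0.1, seed = 1))
#' paths <- write_ped_map(sim$genotypes, sim$snps,
#'                        file.path(tempdir(), "toy"))
#' rt <- read_ped_map(paths$ped, paths$map)
#' identical(unclass(rt$genotypes), unclass(sim$genotypes))
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) rlang::abort(paste0("PED file not found: ", ped_path))
  if (!file.exists(map_path)) rlang::abort(paste0("MAP file not found: ", map_path))
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  n_f <- lengths(map_fields)
  if (length(map_fields) && any(n_f != 4L)) {
    rlang::abort(sprintf("MAP line %d: expected 4 columns, found %d",
                         which(n_f != 4L)[1], n_f[which(n_f != 4L)[1]]))
  }
  snps <- tibble::tibble(
    scaffold = purrr::map_chr(map_fields, 1, .default = NA),
    snp_id = purrr::map_chr(map_fields, 2, .default = NA),
    position = as.integer(purrr::map_chr(map_fields, 4, .default = NA))
  )
  if (nrow(snps) && any(snps$position < 1, na.rm = TRUE)) {
    rlang::abort("MAP positions must be >= 1")
  }
  n_snps <- nrow(snps)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n_ind <- length(ped_lines)
  calls <- matrix(NA_integer_, n_ind, n_snps)
  ids <- character(n_ind)
  a_mat <- matrix(NA_character_, n_ind, n_snps)  # first allele of each pair
  b_mat <- matrix(NA_character_, n_ind, n_snps)
  for (i in seq_len(n_ind)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * n_snps) {
      rlang::abort(sprintf("PED line %d: expected %d fields, found %d",
                           i, 6L + 2L * n_snps, length(f)))
    }
    ids[i] <- f[2]
    if (n_snps) {
      a_mat[i, ] <- f[seq(7L, by = 2L, length.out = n_snps)]
      b_mat[i, ] <- f[seq(8L, by = 2L, length.out = n_snps)]
    }
  }
  allele1 <- rep(NA_character_, n_snps)
  allele2 <- rep(NA_character_, n_snps)
  for (j in seq_len(n_snps)) {
    a <- a_mat[, j]
    b <- b_mat[, j]
    miss <- a == "0" | b == "0"
    obs <- c(a[!miss], b[!miss])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L) {
      rlang::abort(sprintf(
        "SNP %s (MAP line %d): more than two alleles observed (%s)",
        snps$snp_id[j], j, paste(alleles, collapse = ", ")))
    }
    if (length(alleles) == 0L) {
      calls[, j] <- NA_integer_
      next
    }
    if (length(alleles) == 1L) {
      allele1[j] <- alleles
      calls[!miss, j] <- 0L
      next
    }
    n1 <- sum(obs == alleles[1])
    n2 <- sum(obs == alleles[2])
    # alternate = minor allele; tie -> lexicographically greater
    if (n2 < n1 || (n2 == n1)) {
      maj <- alleles[1]; mnr <- alleles[2]
    } else {
      maj <- alleles[2]; mnr <- alleles[1]
    }
    allele1[j] <- maj
    allele2[j] <- mnr
    calls[!miss, j] <- (a[!miss] == mnr) + (b[!miss] == mnr)
  }
  snps$allele1 <- allele1
  snps$allele2 <- allele2
  snps <- snps[, c("snp_id", "scaffold", "position", "allele1", "allele2")]
  list(
    genotypes = geno_matrix(calls, ids = ids, snp_ids = snps$snp_id),
    snps = snps
  )
}

#' Write PLINK text PED/MAP genotypes
#'
#' Inverse of [read_ped_map()] on its supported dialect: allele labels from
#' the SNP table are preserved, missing calls are written as `0 0`.
#'
#' @param g A [geno_matrix()].
#' @param snps SNP tibble as returned by [read_ped_map()] (columns `snp_id`,
#'   `scaffold`, `position`, `allele1`, `allele2`).
#' @param prefix Output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return Invisibly, a list with the two file paths.
#' @export
write_ped_map <- function(g, snps, prefix) {
  g <- as_geno_matrix(g)
  if (nrow(snps) != n_snp(g)) {
    rlang::abort("SNP table rows must match genotype matrix columns")
  }
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  writeLines(
    sprintf("%s\t%s\t0\t%d", snps$scaffold, snps$snp_id, snps$position),
    map_path
  )
  m <- unclass(g)
  a1 <- ifelse(is.na(snps$allele1), "A", snps$allele1)
  a2 <- ifelse(is.na(snps$allele2), "N", snps$allele2)
  lines <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    gi <- m[i, ]
    first <- ifelse(is.na(gi), "0", ifelse(gi >= 1L, a2, a1))
    second <- ifelse(is.na(gi), "0", ifelse(gi == 2L, a2, a1))
    pairs <- as.vector(rbind(first, second))
    lines[i] <- paste(c(rownames(m)[i], rownames(m)[i], "0", "0", "0", "-9",
                        pairs), collapse = "\t")
  }
  writeLines(lines, ped_path)
  invisible(list(ped = ped_path, map = map_path))
}

#' Read gene intervals from a GFF3 annotation
#'
#' Returns features of type `gene` with 1-based inclusive coordinates. The
#' gene name is taken from the `Name=` attribute, falling back to `ID=`.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `scaffold`, `start`, `end`, `gene`.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("GFF file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    rlang::abort(sprintf("GFF line %d: expected 9 tab-separated columns, found %d",
                         idx[which(nf != 9L)[1]], nf[which(nf != 9L)[1]]))
  }
  types <- purrr::map_chr(fields, 3)
  gene_rows <- which(types == "gene")
  out <- purrr::map_dfr(gene_rows, function(k) {
    f <- fields[[k]]
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start > end) {
      rlang::abort(sprintf("GFF line %d: invalid coordinates %s..%s",
                           idx[k], f[4], f[5]))
    }
    attrs <- f[9]
    name <- .gff_attr(attrs, "Name")
    if (is.na(name)) name <- .gff_attr(attrs, "ID")
    if (is.na(name)) {
      rlang::abort(sprintf("GFF line %d: gene feature without Name= or ID= attribute",
                           idx[k]))
    }
    tibble::tibble(scaffold = f[1], start = start, end = end, gene = name)
  })
  if (!nrow(out)) {
    out <- tibble::tibble(scaffold = character(), start = integer(),
                          end = integer(), gene = character())
  }
  out
}

.gff_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attrs))[[1]]
  if (length(m) == 2L) m[2] else NA_character_
}

#' Read a habitat polygon
#'
#' The polygon is given as whitespace-separated `lon lat` vertex lines. At
#' least three distinct vertices are required; an unclosed ring is closed
#' automatically, orientation is normalized to counterclockwise, and a
#' self-intersecting ring is rejected.
#'
#' @param path Path to the polygon file.
#' @return Tibble with columns `lon`, `lat`; the first vertex is not
#'   repeated at the end (the ring closure is implicit).
#' @export
read_polygon <- function(path) {
  tab <- utils::read.table(path, col.names = c("lon", "lat"))
  poly <- tibble::tibble(lon = as.numeric(tab$lon), lat = as.numeric(tab$lat))
  if (nrow(poly) >= 2 &&
      poly$lon[1] == poly$lon[nrow(poly)] && poly$lat[1] == poly$lat[nrow(poly)]) {
    poly <- poly[-nrow(poly), ]
  }
  if (nrow(poly) < 3) rlang::abort("a polygon needs at least 3 distinct vertices")
  if (.ring_self_intersects(poly$lon, poly$lat)) {
    rlang::abort("polygon ring is self-intersecting")
  }
  # normalize to counterclockwise (positive shoelace area)
  if (.shoelace(poly$lon, poly$lat) < 0) {
    poly <- poly[rev(seq_len(nrow(poly))), ]
  }
  tibble::as_tibble(poly)
}

.shoelace <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# O(n^2) check of non-adjacent edge pairs for proper crossings
.ring_self_intersects <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    for (j in seq((i + 2), n)) {
      if (i == 1 && j == n) next  # adjacent through the closure
      d1 <- cross(x2[i] - x[i], y2[i] - y[i], x[j] - x[i], y[j] - y[i])
      d2 <- cross(x2[i] - x[i], y2[i] - y[i], x2[j] - x[i], y2[j] - y[i])
      d3 <- cross(x2[j] - x[j], y2[j] - y[j], x[i] - x[j], y[i] - y[j])
      d4 <- cross(x2[j] - x[j], y2[j] - y[j], x2[i] - x[j], y2[i] - y[j])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Read or validate a sample metadata table
#'
#' Metadata drives every grouping in the pipeline: per-sample country
#' (ISO-2), continent, population label and optional coordinates. When the
#' `continent` column is absent it is derived from a bundled
#' country-to-continent map; when present it is checked against that map.
#'
#' @param path Path to a TSV with columns `sample_id`, `country`, and
#'   optionally `continent`, `population`, `longitude`, `latitude`.
#' @return Tibble with all six columns (missing optional ones filled with
#'   `NA`; `population` defaults to the country code).
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_metadata(meta)
}

#' @rdname read_sample_metadata
#' @param meta A data frame of sample metadata.
#' @export
validate_sample_metadata <- function(meta) {
  meta <- tibble::as_tibble(meta)
  if (!all(c("sample_id", "country") %in% names(meta))) {
    rlang::abort("metadata needs at least `sample_id` and `country` columns")
  }
  if (anyDuplicated(meta$sample_id)) rlang::abort("duplicate sample ids in metadata")
  mapped <- unname(country_continent_map()[meta$country])
  if (!"continent" %in% names(meta)) {
    meta$continent <- mapped
  } else {
    known <- !is.na(mapped)
    bad <- known & !is.na(meta$continent) & meta$continent != mapped
    if (any(bad)) {
      rlang::abort(paste0(
        "continent inconsistent with country for: ",
        paste(meta$sample_id[bad], collapse = ", ")))
    }
  }
  if (!"population" %in% names(meta)) meta$population <- meta$country
  if (!"longitude" %in% names(meta)) meta$longitude <- NA_real_
  if (!"latitude" %in% names(meta)) meta$latitude <- NA_real_
  meta[, c("sample_id", "country", "continent", "population",
           "longitude", "latitude")]
}

#' Bundled country-to-continent map
#'
#' ISO-2 codes for the dromedary distribution range (Africa and Asia).
#' Breed labels such as the Saudi *Hadhana* are population labels, not
#' countries, and are not in this map.
#'
#' @return Named character vector, country code -> continent.
#' @export
country_continent_map <- function() {
  c(
    # Africa
    DZ = "Africa", EG = "Africa", ET = "Africa", KE = "Africa", LY = "Africa",
    ML = "Africa", MA = "Africa", MR = "Africa", NE = "Africa", NG = "Africa",
    SD = "Africa", SO = "Africa", TD = "Africa", TN = "Africa", DJ = "Africa",
    ER = "Africa", EH = "Africa", BF = "Africa",
    # Asia
    AE = "Asia", AF = "Asia", BH = "Asia", IN = "Asia", IQ = "Asia",
    IR = "Asia", JO = "Asia", KW = "Asia", KZ = "Asia", MN = "Asia",
    OM = "Asia", PK = "Asia", QA = "Asia", SA = "Asia", SY = "Asia",
    TM = "Asia", TR = "Asia", UZ = "Asia", YE = "Asia", IL = "Asia"
  )
}

#' Write a square PHYLIP-style distance matrix
#'
#' The format consumed by phylogenetic-network tools: first line the number
#' of taxa, then one row per taxon with its id and all distances.
#'
#' @param d Symmetric numeric matrix with row/column names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phylip_distance <- function(d, path) {
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    rlang::abort("distance matrix must be symmetric")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(rownames(d)[i], formatC(d[i, ], format = "g", digits = 8)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read and write RAD-locus FASTA alignments
#'
#' One FASTA per locus: ingroup individuals as IUPAC-coded diploid consensus
#' sequences plus one outgroup sequence whose name carries the `outgroup`
#' prefix.
#'
#' @param loci A RAD locus set as returned by [simulate_rad_loci()].
#' @param dir Directory to write one `<locus_id>.fasta` per locus into.
#' @return `write_rad_fasta()` invisibly returns the file paths;
#'   `read_rad_fasta()` returns a RAD locus set tibble.
#' @export
write_rad_fasta <- function(loci, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_chr(seq_len(nrow(loci)), function(k) {
    p <- file.path(dir, paste0(loci$locus_id[k], ".fasta"))
    seqs <- c(loci$sequences[[k]],
              stats::setNames(loci$outgroup[k], "outgroup"))
    writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), p)
    p
  })
  invisible(paths)
}

#' @rdname write_rad_fasta
#' @export
read_rad_fasta <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (!length(files)) rlang::abort(paste0("no .fasta files in ", dir))
  rows <- purrr::map_dfr(files, function(f) {
    lines <- readLines(f)
    heads <- grep("^>", lines)
    names <- sub("^>", "", lines[heads])
    ends <- c(heads[-1] - 1L, length(lines))
    seqs <- purrr::map2_chr(heads + 1L, ends,
                            function(a, b) paste(lines[a:b], collapse = ""))
    names(seqs) <- names
    og <- grepl("^outgroup", names)
    if (sum(og) != 1L) {
      rlang::abort(paste0(f, ": expected exactly one outgroup sequence"))
    }
    ing <- seqs[!og]
    if (length(unique(nchar(c(ing, seqs[og])))) != 1L) {
      rlang::abort(paste0(f, ": sequences have unequal lengths"))
    }
    tibble::tibble(
      locus_id = sub("\\.fasta$", "", basename(f)),
      length = nchar(seqs[og][[1]]),
      n_snps = count_segregating_sites(ing),
      presence = NA_real_,
      sequences = list(ing),
      outgroup = unname(seqs[og])
    )
  })
  rows
}

#' Count segregating sites in an IUPAC-coded alignment
#'
#' A site segregates when more than one underlying allele is present among
#' the ingroup sequences; IUPAC heterozygote codes contribute both of their
#' alleles.
#'
#' @param seqs Named character vector of equal-length sequences.
#' @return Integer count.
#' @export
count_segregating_sites <- function(seqs) {
  if (!length(seqs)) return(0L)
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  amb <- iupac_alleles()
  seg <- 0L
  for (j in seq_len(ncol(mat))) {
    alleles <- unique(unlist(amb[mat[, j]], use.names = FALSE))
    alleles <- setdiff(alleles, "N")
    if (length(alleles) > 1L) seg <- seg + 1L
  }
  seg
}

# IUPAC code -> underlying alleles (bases map to themselves)
iupac_alleles <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
       W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
       N = "N", `-` = "N")
}

iupac_code <- function(a, b) {
  if (a == b) return(a)
  key <- paste(sort(c(a, b)), collapse = "")
  c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")[[key]]
}
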