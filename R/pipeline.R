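#' Run the full analysis pipeline from a config
#'
#' Orchestrates the stages in the study's order — hybrid screen, QC filter
#' cascade, diversity and differentiation statistics, PCA and ancestry
#' clustering, FST-outlier scan, migration surface, demographic input
#' preparation — each stage consuming the previous stage's outputs. The
#' config is a plain key-value list (or a YAML file path) with input paths,
#' filter parameters, stage toggles and seeds. Every stage writes its
#' tables under `output_dir` and is recorded, with wall time, in the run
#' report; the report plus the embedded config suffice to reproduce the
#' run.
#'
#' @param config A list or path to a YAML file. Recognized keys:
#'   `ped`, `map`, `metadata`, `counts`, `gff`, `polygon` (input paths);
#'   `output_dir`; `seed`; `filter` (sub-list with `max_ind_missing`,
#'   `min_maf`, `max_geno_missing`, `ibs_cutoff`); `stages` (character
#'   vector naming the stages to run, default all of
#'   `hybrid_screen`, `filter`, `stats`, `structure`, `scan`,
#'   `migration_surface`, `demographic_prep`); `group_by` (grouping column
#'   for stats/scan, default `"continent"`); `n_demes`; `K_range`;
#'   `n_perm`; `loci_dir` (RAD-locus FASTA directory for demographic prep).
#' @return Invisibly, a list with per-stage results and `report` (tibble of
#'   stage, status, wall seconds); the report is also written as
#'   `run_report.yaml` in the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  all_stages <- c("hybrid_screen", "filter", "stats", "structure", "scan",
                  "migration_surface", "demographic_prep")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) {
    rlang::abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  out_dir <- config$output_dir %||% rlang::abort("config needs `output_dir`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  group_by <- config$group_by %||% "continent"

  results <- list()
  report <- tibble::tibble(stage = character(), status = character(),
                           seconds = numeric())
  note <- function(stage, status, secs) {
    report <<- dplyr::bind_rows(report, tibble::tibble(
      stage = stage, status = status, seconds = round(secs, 2)))
  }
  run_stage <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      note(stage, paste0("error: ", conditionMessage(e)),
           proc.time()[["elapsed"]] - t0)
      .write_report(report, config, out_dir)
      rlang::abort(paste0("stage `", stage, "` failed: ", conditionMessage(e)))
    })
    note(stage, "ok", proc.time()[["elapsed"]] - t0)
    res
  }

  need <- function(key) {
    config[[key]] %||% rlang::abort(paste0("config needs `", key, "`"))
  }

  # --- load shared inputs
  geno <- NULL
  snps <- NULL
  meta <- NULL
  if (!is.null(config$ped)) {
    pm <- read_ped_map(need("ped"), need("map"))
    geno <- pm$genotypes
    snps <- pm$snps
  }
  if (!is.null(config$metadata)) meta <- read_sample_metadata(config$metadata)

  flagged <- character()
  if ("hybrid_screen" %in% stages) {
    results$hybrid_screen <- run_stage("hybrid_screen", function() {
      counts <- readr::read_tsv(need("counts"), show_col_types = FALSE,
                                progress = FALSE)
      scr <- flag_hybrids(counts)
      readr::write_tsv(tidy(scr), file.path(out_dir, "hybrid_screen.tsv"))
      scr
    })
    flagged <- results$hybrid_screen$flagged
    if (!is.null(geno)) {
      keep <- setdiff(rownames(geno), flagged)
      geno <- geno[keep, , drop = FALSE]
    }
  }

  if ("filter" %in% stages) {
    results$filter <- run_stage("filter", function() {
      if (is.null(geno)) rlang::abort("filter stage needs `ped`/`map` inputs")
      fp <- do.call(filter_params, config$filter %||% list())
      casc <- run_filter_cascade(geno, fp)
      readr::write_tsv(
        tidyr::unnest(tidy(casc), "removed", keep_empty = TRUE),
        file.path(out_dir, "filter_report.tsv"))
      kept_snps <- snps[snps$snp_id %in% colnames(casc$genotypes), ]
      write_ped_map(casc$genotypes, kept_snps,
                    file.path(out_dir, "filtered"))
      casc
    })
    geno <- results$filter$genotypes
    snps <- snps[snps$snp_id %in% colnames(geno), ]
  }

  groups_of <- function() {
    if (is.null(meta)) rlang::abort("this stage needs `metadata`")
    resolve_groups(geno, meta, group_by)
  }

  if ("stats" %in% stages) {
    results$stats <- run_stage("stats", function() {
      if (is.null(geno)) rlang::abort("stats stage needs genotypes")
      div <- diversity_summary(geno, meta, if (!is.null(meta)) group_by)
      readr::write_tsv(div, file.path(out_dir, "diversity.tsv"))
      fst <- pairwise_fst(geno, meta, group_by,
                          n_perm = config$n_perm %||% 1000, seed = seed)
      readr::write_tsv(fst, file.path(out_dir, "pairwise_fst.tsv"))
      am <- amova(geno, groups_of(), n_perm = config$n_perm %||% 1000,
                  seed = seed)
      readr::write_tsv(tidy(am), file.path(out_dir, "amova.tsv"))
      list(diversity = div, fst = fst, amova = am)
    })
  }

  if ("structure" %in% stages) {
    results$structure <- run_stage("structure", function() {
      if (is.null(geno)) rlang::abort("structure stage needs genotypes")
      pc <- pca_genotypes(geno)
      readr::write_tsv(pc$scores, file.path(out_dir, "pca_scores.tsv"))
      readr::write_tsv(tidy(pc), file.path(out_dir, "pca_eigen.tsv"))
      cv <- admixture_cv(geno, K_range = config$K_range %||% 1:5, seed = seed)
      readr::write_tsv(cv$summary, file.path(out_dir, "admixture_cv.tsv"))
      fit <- admixture_fit(geno, max(2L, cv$best_K), seed = seed)
      readr::write_tsv(tidy(fit), file.path(out_dir, "admixture_Q.tsv"))
      d <- allele_sharing_distance(geno)
      write_phylip_distance(d, file.path(out_dir, "allele_sharing.phy"))
      list(pca = pc, cv = cv, fit = fit)
    })
  }

  if ("scan" %in% stages) {
    results$scan <- run_stage("scan", function() {
      if (is.null(geno)) rlang::abort("scan stage needs genotypes")
      counts <- allele_counts_by_group(geno, groups_of())
      scan <- bayescan_fit(counts, seed = seed,
                           fdr = config$fdr %||% 0.05)
      readr::write_tsv(tidy(scan), file.path(out_dir, "outlier_scan.tsv"))
      ann <- NULL
      if (!is.null(config$gff)) {
        genes <- read_gff_genes(config$gff)
        out_snps <- dplyr::inner_join(
          snps, dplyr::filter(tidy(scan), .data$outlier), by = "snp_id")
        ann <- annotate_windows(out_snps, genes,
                                flank = config$flank %||% 200000)
        readr::write_tsv(ann, file.path(out_dir, "outlier_genes.tsv"))
      }
      list(scan = scan, annotation = ann)
    })
  }

  if ("migration_surface" %in% stages) {
    results$migration_surface <- run_stage("migration_surface", function() {
      if (is.null(geno)) rlang::abort("migration stage needs genotypes")
      if (is.null(meta)) rlang::abort("migration stage needs metadata")
      poly <- read_polygon(need("polygon"))
      grid <- build_deme_grid(poly, config$n_demes %||% 50)
      meta_g <- meta[match(rownames(geno), meta$sample_id), ]
      dem <- assign_demes(grid, meta_g)
      surf <- fit_migration_surface(
        observed_dissimilarity(geno), grid, dem,
        n_iter = config$mig_iters %||% 2000, seed = seed)
      cls <- classify_surface(surf)
      readr::write_tsv(cls, file.path(out_dir, "migration_surface.tsv"))
      list(surface = surf, classes = cls)
    })
  }

  if ("demographic_prep" %in% stages) {
    results$demographic_prep <- run_stage("demographic_prep", function() {
      loci <- read_rad_fasta(need("loci_dir"))
      n_sel <- min(config$n_loci %||% 50, nrow(loci))
      sel <- select_ebsp_loci(loci, n = n_sel, seed = seed)
      cal <- clock_rate(sel)
      nx <- export_nexus(sel, file.path(out_dir, "nexus"), calibration = cal)
      list(selected = sel, calibration = cal, manifest = nx$manifest)
    })
  }

  .write_report(report, config, out_dir)
  invisible(c(results, list(report = report)))
}

.write_report <- function(report, config, out_dir) {
  yaml::write_yaml(
    list(package_version = as.character(utils::packageVersion("camelroutes")),
         seed = config$seed %||% 1L,
         config = config[setdiff(names(config), "stages_internal")],
         stages = purrr::pmap(report, function(stage, status, seconds) {
           list(stage = stage, status = status, seconds = seconds)
         })),
    file.path(out_dir, "run_report.yaml"))
}
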