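default_config <- function() {
  list(
    seed = 1L,
    simulate = list(),                       # sim_config() arguments
    qc = list(max_missing = 0.25, min_maf = 0.05),
    gwas = list(n_pcs = 6, cofactors = "anthesis", fdr_alpha = 0.05,
                effective_markers = 3696, suggestive = 3,
                environments = NULL),
    hotspots = list(high_mult = 5, window_mult = 1, max_ci_mb = 35,
                    min_years = 2, min_traits = 2,
                    threshold = "suggestive"),
    inputs = NULL                            # external file paths, optional
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Configurations are YAML (or plain lists) with blocks `simulate`
#' (arguments to [sim_config()]) or `inputs` (paths to external genotype,
#' phenotype, map, LD-decay and centromere files), plus per-stage
#' parameter blocks `qc`, `gwas` and `hotspots`. All study thresholds
#' surface here with their conventional defaults (missingness 0.25, MAF
#' 0.05, 6 PCs, suggestive -log10 p 3, alpha 0.05, 3,696 effective
#' markers, 35 Mb, at least 2 years and 2 traits, high threshold 5x the
#' map-wide mean). Referenced paths are checked before any stage runs.
#'
#' @param config Path to a YAML file, or a list.
#' @return Validated configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  if (!is.null(cfg$inputs)) {
    required <- c("genotypes", "phenotypes", "map", "ld_decay", "centromeres")
    miss <- setdiff(required, names(cfg$inputs))
    if (length(miss)) {
      stop("config `inputs` block is missing: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    for (p in unlist(cfg$inputs)) {
      if (!file.exists(p)) stop("input file does not exist: ", p, call. = FALSE)
    }
  }
  if (!is.null(cfg$simulate$planted_qtls)) {
    cfg$simulate$planted_qtls <- dplyr::bind_rows(cfg$simulate$planted_qtls)
  }
  if (!is.null(cfg$simulate$h2_targets)) {
    cfg$simulate$h2_targets <- unlist(cfg$simulate$h2_targets)
  }
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full simulate-to-hotspots pipeline
#'
#' Orchestrates: genotype simulation (or external input loading), marker
#' QC, multi-year phenotype simulation, reflectance and vegetation-index
#' computation, per-trait-per-environment mixed-model GWAS scans,
#' suggestive-threshold MTA selection, the QTL overview index, peak
#' calling, hotspot merging, and the exclusion rules. All randomness
#' derives from the configuration seed, so a rerun with the same
#' configuration reproduces identical hotspot tables.
#'
#' @param config A configuration ([pipeline_config()]), a YAML path, or a
#'   list of overrides.
#' @param outdir Optional output directory; when given, every stage
#'   product is written as CSV/BED together with a manifest of file MD5
#'   hashes.
#' @return List with `panel`, `qc_report`, `phenotypes`, `ground_truth`,
#'   `vi`, `scans` (full scan records), `mtas` (thresholded), `thresholds`,
#'   `profile`, `peaks`, `hotspots` (retained), `excluded`, and `manifest`.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  cfg <- pipeline_config(config)
  log_msg <- function(...) message("[qtlhotspots] ", sprintf(...))

  if (is.null(cfg$inputs)) {
    sim <- run_stage("simulate", do.call(
      sim_config, c(cfg$simulate, list(seed = cfg$seed))))
    log_msg("simulating %d accessions x %d markers",
            sim$n_accessions, sum(sim$markers_per_chrom))
    panel0 <- run_stage("simulate", simulate_genotypes(sim))
    ph <- run_stage("phenotypes", simulate_phenotypes(panel0, sim))
    phenotypes <- ph$phenotypes
    truth <- ph$ground_truth
    spectra <- run_stage("reflectance", dplyr::bind_rows(
      simulate_reflectance(panel0, truth, "anthesis", sim),
      simulate_reflectance(panel0, truth, "postanthesis", sim)))
    ld <- ld_profile(panel0$chrom_info$chromosome,
                     panel0$chrom_info$ld_decay_cm)
    map_lengths <- panel0$chrom_info[, c("chromosome", "length_cm")]
    centromeres <- panel0$chrom_info[, c("chromosome", "centromere_cm")]
  } else {
    inp <- cfg$inputs
    fmt <- if (grepl("\\.vcf$", inp$genotypes)) "vcf" else "matrix"
    panel0 <- run_stage("load", read_genotypes(inp$genotypes, fmt,
                                               map = inp$map))
    phenotypes <- run_stage("load", readr::read_csv(inp$phenotypes,
                                                    show_col_types = FALSE))
    truth <- NULL
    spectra <- NULL
    ld <- normalize_ld(readr::read_csv(inp$ld_decay, show_col_types = FALSE))
    ml_raw <- dplyr::summarise(
      dplyr::group_by(panel0$map, .data$chromosome),
      length_cm = max(.data$cm), .groups = "drop")
    map_lengths <- ml_raw
    centromeres <- readr::read_csv(inp$centromeres, show_col_types = FALSE)
  }

  qc <- run_stage("qc", qc_filter(panel0, cfg$qc$max_missing, cfg$qc$min_maf))
  panel <- qc$panel
  log_msg("QC: %d of %d markers retained", ncol(panel$dosages),
          ncol(panel0$dosages))

  vi <- if (!is.null(spectra)) {
    run_stage("vi", compute_vi(spectra))
  } else NULL

  means <- run_stage("gwas", accession_means(phenotypes))
  wide <- tidyr::pivot_wider(means, names_from = "trait",
                             values_from = "value")
  traits <- unique(phenotypes$trait)
  envs <- cfg$gwas$environments %||% unique(means$environment)
  cof_all <- intersect(cfg$gwas$cofactors %||% character(), traits)
  scans <- run_stage("gwas", purrr::map_dfr(traits, function(tr) {
    purrr::map_dfr(envs, function(ev) {
      w <- dplyr::filter(wide, .data$environment == ev)
      mlm_scan(panel, w, trait = tr, environment = ev,
               cofactors = setdiff(cof_all, tr), n_pcs = cfg$gwas$n_pcs)
    })
  }))
  thresholds <- gwas_thresholds(cfg$gwas$suggestive, cfg$gwas$fdr_alpha,
                                cfg$gwas$effective_markers)
  thr <- if (identical(cfg$hotspots$threshold, "corrected")) {
    thresholds$corrected
  } else {
    thresholds$suggestive
  }
  mtas <- dplyr::filter(tibble::as_tibble(scans), .data$neglog10p > thr)
  log_msg("%d MTAs above -log10 p > %.3g from %d scans", nrow(mtas), thr,
          length(traits) * length(envs))

  profile <- run_stage("hotspots", overview_index(
    mtas, ld, map_lengths, high_mult = cfg$hotspots$high_mult))
  peaks <- run_stage("hotspots", call_peaks(
    profile, mean_mult = 1, high_mult = cfg$hotspots$high_mult))
  high <- dplyr::filter(peaks, .data$tier == "high")
  hotspots_all <- if (nrow(high)) {
    run_stage("hotspots", merge_to_hotspots(
      high, mtas, ld, panel$map, map_lengths,
      window_mult = cfg$hotspots$window_mult))
  } else {
    log_msg("no peaks above the high threshold")
    NULL
  }
  retained <- if (!is.null(hotspots_all)) {
    run_stage("hotspots", filter_hotspots(
      hotspots_all, centromeres, cfg$hotspots$max_ci_mb,
      cfg$hotspots$min_years, cfg$hotspots$min_traits))
  } else NULL
  log_msg("%d hotspot(s) retained of %d merged",
          if (is.null(retained)) 0L else nrow(retained),
          if (is.null(hotspots_all)) 0L else nrow(hotspots_all))

  manifest <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(obj, file) {
      path <- file.path(outdir, file)
      if (!is.null(obj)) readr::write_csv(tibble::as_tibble(obj), path)
      path
    }
    files <- c(
      wr(phenotypes, "phenotypes.csv"),
      wr(qc$report, "qc_report.csv"),
      wr(vi, "vegetation_indices.csv"),
      wr(scans, "scan_records.csv"),
      wr(mtas, "mtas.csv"),
      wr(profile, "overview_index.csv"),
      wr(peaks, "peaks.csv"),
      if (!is.null(retained)) {
        wr(dplyr::select(retained, -"member_mtas"), "hotspots.csv")
      })
    write_genotypes(panel, file.path(outdir, "genotypes_qc.vcf"), "vcf")
    files <- c(files, file.path(outdir, "genotypes_qc.vcf"))
    if (!is.null(retained) && nrow(retained)) {
      hotspots_to_bed(retained, file.path(outdir, "hotspots.bed"))
      files <- c(files, file.path(outdir, "hotspots.bed"))
    }
    files <- files[file.exists(files)]
    manifest <- tibble::tibble(
      file = basename(files),
      md5 = unname(tools::md5sum(files)),
      seed = cfg$seed)
    readr::write_csv(manifest, file.path(outdir, "manifest.csv"))
  }

  list(panel = panel, qc_report = qc$report, phenotypes = phenotypes,
       ground_truth = truth, vi = vi, scans = scans, mtas = mtas,
       thresholds = thresholds, profile = profile, peaks = peaks,
       hotspots = retained, excluded = attr(retained, "excluded"),
       manifest = manifest, config = cfg)
}
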