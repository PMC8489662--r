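#' Assemble a genotype panel from its parts
#'
#' @param dosages Accession x marker matrix with values in `{0, 1, 2, NA}`.
#' @param map Tibble with `marker_id`, `chromosome`, `cm`, `bp`, sorted by
#'   chromosome then cM (enforced).
#' @param accessions Optional tibble with `accession_id` (and extras such as
#'   `subpop`); defaults to the dosage rownames.
#' @param chrom_info Optional per-chromosome tibble (lengths, centromere,
#'   LD decay) carried along for downstream stages.
#' @return A `genotype_panel`.
#' @export
genotype_panel <- function(dosages, map, accessions = NULL, chrom_info = NULL) {
  stopifnot(is.matrix(dosages), !is.null(rownames(dosages)),
            !is.null(colnames(dosages)))
  bad <- setdiff(unique(as.vector(dosages)), c(0L, 1L, 2L, NA))
  if (length(bad)) stop("dosages must be in {0, 1, 2, NA}; found: ",
                        paste(bad, collapse = ", "))
  map <- tibble::as_tibble(map)
  stopifnot(all(c("marker_id", "chromosome", "cm", "bp") %in% names(map)),
            setequal(map$marker_id, colnames(dosages)))
  map <- dplyr::arrange(map, .data$chromosome, .data$cm, .data$bp)
  dosages <- dosages[, map$marker_id, drop = FALSE]
  if (is.null(accessions)) {
    accessions <- tibble::tibble(accession_id = rownames(dosages))
  }
  structure(list(dosages = dosages, map = map,
                 accessions = tibble::as_tibble(accessions),
                 chrom_info = chrom_info),
            class = "genotype_panel")
}

#' Read a genotype panel from VCF or matrix CSV
#'
#' The VCF reader keeps biallelic SNP records only; multi-allelic records are
#' dropped with a warning reporting the count. Genetic (cM) positions are
#' read from the `CM` INFO field when present (as written by
#' [write_genotypes()]). The matrix-CSV dialect is an `accession_id` column
#' followed by one column per marker; the map must then be supplied via
#' `map` (a data frame or the path of a map CSV with columns `marker_id`,
#' `chromosome`, `cm`, `bp`).
#'
#' @param path Input file path.
#' @param format `"vcf"` or `"matrix"`.
#' @param map Marker map for `format = "matrix"`.
#' @return A `genotype_panel`.
#' @export
read_genotypes <- function(path, format = c("vcf", "matrix"), map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                                           stringsAsFactors = FALSE))
    multi <- grepl(",", fix$ALT %||% "")
    if (any(multi)) {
      warning(sprintf("dropped %d non-biallelic record(s)", sum(multi)))
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    allele_count <- function(g) {
      g <- sub(":.*", "", g)
      ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_integer_,
             stringr::str_count(g, "1"))
    }
    dos <- t(apply(gt, 2, allele_count))
    dos <- matrix(as.integer(dos), nrow = ncol(gt),
                  dimnames = list(colnames(gt), rownames(gt)))
    info <- fix$INFO %||% rep(NA_character_, nrow(fix))
    cm <- suppressWarnings(as.numeric(stringr::str_match(info, "CM=([0-9.eE+-]+)")[, 2]))
    map <- tibble::tibble(marker_id = fix$ID, chromosome = fix$CHROM,
                          cm = cm, bp = as.numeric(fix$POS))
    genotype_panel(dos, map)
  } else {
    if (is.null(map)) stop("matrix format needs a `map` (data frame or CSV path)")
    if (is.character(map)) {
      map <- readr::read_csv(map, show_col_types = FALSE)
    }
    d <- readr::read_csv(path, show_col_types = FALSE)
    dos <- as.matrix(d[, -1, drop = FALSE])
    storage.mode(dos) <- "integer"
    rownames(dos) <- d[[1]]
    genotype_panel(dos, map)
  }
}

#' Write a genotype panel to VCF or matrix CSV
#'
#' The VCF output is a minimal VCF 4.2 with contig headers, a `CM` INFO
#' field holding the genetic position, and GT-only genotype columns, so a
#' write-read round trip preserves dosages and both map coordinates. The
#' matrix output writes `<path>` (dosage CSV) and, unless `map_path` is
#' `NULL`, a companion map CSV.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path.
#' @param format `"vcf"` or `"matrix"`.
#' @param map_path Map CSV path for matrix format (default
#'   `<path>` with a `_map.csv` suffix).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path, format = c("vcf", "matrix"),
                            map_path = NULL) {
  format <- match.arg(format)
  map <- panel$map
  if (format == "vcf") {
    contigs <- unique(map$chromosome)
    hdr <- c("##fileformat=VCFv4.2",
             "##source=qtlhotspots",
             '##INFO=<ID=CM,Number=1,Type=Float,Description="Genetic position in centimorgan">',
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             sprintf("##contig=<ID=%s>", contigs),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(panel$dosages)),
                   collapse = "\t"))
    gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    body <- vapply(seq_len(nrow(map)), function(j) {
      d <- panel$dosages[, map$marker_id[j]]
      g <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
      paste(c(map$chromosome[j], format(map$bp[j], scientific = FALSE),
              map$marker_id[j], "A", "G", ".", "PASS",
              sprintf("CM=%.6g", map$cm[j]), "GT", g), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, body), path)
  } else {
    out <- tibble::as_tibble(panel$dosages, rownames = "accession_id")
    readr::write_csv(out, path)
    if (is.null(map_path)) {
      map_path <- sub("\\.csv$", "_map.csv", path)
      if (identical(map_path, path)) map_path <- paste0(path, "_map.csv")
    }
    readr::write_csv(map, map_path)
  }
  invisible(path)
}

# per-marker summaries on non-missing calls
marker_stats <- function(dosages) {
  n <- nrow(dosages)
  miss <- colMeans(is.na(dosages))
  p <- colMeans(dosages, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  tibble::tibble(marker_id = colnames(dosages), missingness = miss,
                 maf = pmin(p, 1 - p))
}

#' Marker quality control
#'
#' Applies the standard panel filters: markers with missingness above
#' `max_missing` or minor-allele frequency (computed on non-missing calls)
#' below `min_maf` are removed. Markers sharing an identical non-missing
#' dosage pattern with an earlier marker are flagged as duplicates in the
#' report but retained. Retained markers keep their map order, and the
#' filter is idempotent.
#'
#' @param panel A `genotype_panel`.
#' @param max_missing Maximum tolerated per-marker missingness (default
#'   0.25).
#' @param min_maf Minimum minor-allele frequency (default 0.05).
#' @return List with `panel` (filtered) and `report`, a tibble
#'   (`marker_id`, `reason`, `value`) listing removals (`high_missing`,
#'   `low_maf`) and duplicate-pattern flags (`duplicate_pattern`, retained).
#' @export
qc_filter <- function(panel, max_missing = 0.25, min_maf = 0.05) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  st <- marker_stats(panel$dosages)
  report <- dplyr::bind_rows(
    tibble::tibble(marker_id = st$marker_id[st$missingness > max_missing],
                   reason = "high_missing",
                   value = st$missingness[st$missingness > max_missing]),
    tibble::tibble(marker_id = st$marker_id[st$maf < min_maf],
                   reason = "low_maf", value = st$maf[st$maf < min_maf]))
  keep <- setdiff(st$marker_id, report$marker_id)
  if (!length(keep)) {
    stop("qc_filter: no markers remain after filtering", call. = FALSE)
  }
  # duplicate non-missing dosage patterns among retained markers
  pat <- apply(panel$dosages[, keep, drop = FALSE], 2, function(v) {
    paste(ifelse(is.na(v), ".", v), collapse = "")
  })
  dup <- keep[duplicated(pat)]
  if (length(dup)) {
    report <- dplyr::bind_rows(
      report, tibble::tibble(marker_id = dup, reason = "duplicate_pattern",
                             value = NA_real_))
  }
  out <- genotype_panel(panel$dosages[, keep, drop = FALSE],
                        panel$map[panel$map$marker_id %in% keep, ],
                        panel$accessions, panel$chrom_info)
  list(panel = out, report = report)
}
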