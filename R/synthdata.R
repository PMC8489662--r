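#' Simulation configuration for a structured wheat panel
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate the study system the package targets: a Mediterranean bread-wheat
#' association panel of 354 accessions structured into six genetic
#' subpopulations, genotyped at roughly 10,000 mapped SNPs over 21
#' chromosomes, phenotyped for three seasons in an augmented design with two
#' replicated checks at a 1:4 check-to-test ratio.
#'
#' @param n_accessions Number of accessions in the panel.
#' @param n_subpops Number of genetic subpopulations.
#' @param fst Wright's FST differentiation among subpopulations, in (0, 1).
#' @param n_chromosomes Number of chromosomes.
#' @param markers_per_chrom Markers per chromosome (length 1 or
#'   `n_chromosomes`).
#' @param map_length_cm Genetic length per chromosome in centimorgan.
#' @param chrom_length_bp Physical length per chromosome in base pairs.
#' @param ld_decay_cm Linkage-disequilibrium decay distance per chromosome
#'   (cM); also the scale of founder-haplotype correlation.
#' @param centromere_cm Centromere position per chromosome (cM), strictly
#'   inside (0, map_length_cm).
#' @param planted_qtls Data frame with columns `chrom`, `cm`, `trait`,
#'   `effect` (fraction of plot-level phenotypic variance), or `NULL`.
#'   Markers are placed at the planted genetic positions.
#' @param years Character vector of year labels.
#' @param h2_targets Named numeric vector of per-trait broad-sense
#'   heritabilities in `[0, 1]`; names define the simulated traits.
#' @param e_share Fraction of the non-genetic core variance `1 - h2`
#'   assigned to the year main effect (the rest is genotype-by-year).
#' @param sigma2_res Plot residual variance, on top of the unit core
#'   variance `sigma2_G + sigma2_E + sigma2_GE = 1`.
#' @param sigma2_row,sigma2_col Field row and column effect variances.
#' @param check_ratio Checks-to-test plot ratio (0.25 means 1 check plot
#'   per 4 test plots).
#' @param missing_rate Per-marker missing-call rate ceiling in `[0, 0.25]`.
#' @param maf_floor Minimum observed minor-allele frequency enforced on the
#'   simulated markers, in `(0, 0.5)`.
#' @param founders_per_subpop Founder haplotypes per subpopulation in the
#'   mosaic model.
#' @param seed Integer seed; fully determines every generated artifact.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_accessions = 60, n_chromosomes = 2,
#'                   markers_per_chrom = 50, seed = 7)
sim_config <- function(n_accessions = 354,
                       n_subpops = 6,
                       fst = 0.2,
                       n_chromosomes = 21,
                       markers_per_chrom = 480,
                       map_length_cm = 160,
                       chrom_length_bp = 7e8,
                       ld_decay_cm = 5,
                       centromere_cm = NULL,
                       planted_qtls = NULL,
                       years = c("2016", "2017", "2018"),
                       h2_targets = c(yield = 0.9),
                       e_share = 0.5,
                       sigma2_res = 0.25,
                       sigma2_row = 0.02,
                       sigma2_col = 0.02,
                       check_ratio = 0.25,
                       missing_rate = 0.03,
                       maf_floor = 0.05,
                       founders_per_subpop = 16,
                       seed = 1L) {
  nc <- n_chromosomes
  if (n_accessions < 1 || nc < 1) stop("non-positive panel dimensions")
  if (!is.numeric(fst) || fst <= 0 || fst >= 1) stop("`fst` must lie in (0, 1)")
  if (missing_rate < 0 || missing_rate > 0.25) {
    stop("`missing_rate` must lie in [0, 0.25]")
  }
  markers_per_chrom <- recycle_chrom(markers_per_chrom, nc, "markers_per_chrom")
  map_length_cm <- recycle_chrom(map_length_cm, nc, "map_length_cm")
  chrom_length_bp <- recycle_chrom(chrom_length_bp, nc, "chrom_length_bp")
  ld_decay_cm <- recycle_chrom(ld_decay_cm, nc, "ld_decay_cm")
  if (is.null(centromere_cm)) centromere_cm <- map_length_cm / 2
  centromere_cm <- recycle_chrom(centromere_cm, nc, "centromere_cm")
  if (any(centromere_cm <= 0 | centromere_cm >= map_length_cm)) {
    stop("`centromere_cm` must lie strictly inside (0, map_length_cm)")
  }
  if (any(markers_per_chrom < 1)) stop("non-positive marker counts")
  if (any(h2_targets < 0 | h2_targets > 1)) stop("`h2_targets` must lie in [0, 1]")
  if (is.null(names(h2_targets)) || any(!nzchar(names(h2_targets)))) {
    stop("`h2_targets` must be a named vector; names define the traits")
  }
  if (!is.null(planted_qtls)) {
    planted_qtls <- tibble::as_tibble(planted_qtls)
    stopifnot(all(c("chrom", "cm", "trait", "effect") %in% names(planted_qtls)))
    vp <- 1 + sigma2_res
    planted <- dplyr::summarise(
      dplyr::group_by(planted_qtls, .data$trait),
      tot = sum(.data$effect) * vp, .groups = "drop")
    for (i in seq_len(nrow(planted))) {
      tr <- planted$tot[i]
      h2 <- h2_targets[[planted$trait[i]]]
      if (!is.null(h2) && !is.na(h2) && tr > h2 + 1e-8) {
        stop(sprintf(
          "planted QTL variance for trait '%s' (%.3f) exceeds its sigma2_G (%.3f)",
          planted$trait[i], tr, h2))
      }
    }
  }
  structure(list(
    n_accessions = as.integer(n_accessions), n_subpops = as.integer(n_subpops),
    fst = fst, n_chromosomes = as.integer(nc),
    markers_per_chrom = as.integer(markers_per_chrom),
    map_length_cm = map_length_cm, chrom_length_bp = chrom_length_bp,
    ld_decay_cm = ld_decay_cm, centromere_cm = centromere_cm,
    planted_qtls = planted_qtls, years = as.character(years),
    h2_targets = h2_targets, e_share = e_share, sigma2_res = sigma2_res,
    sigma2_row = sigma2_row, sigma2_col = sigma2_col,
    check_ratio = check_ratio, missing_rate = missing_rate,
    maf_floor = maf_floor,
    founders_per_subpop = as.integer(founders_per_subpop),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# piecewise-linear physical position for genetic positions on one
# chromosome: the window around the centromere carries a large bp share,
# emulating suppressed pericentromeric recombination
bp_from_cm <- function(cm, length_cm, length_bp, centromere) {
  w <- 0.05 * length_cm
  knots_cm <- c(0, max(centromere - w, 1e-9),
                min(centromere + w, length_cm - 1e-9), length_cm)
  knots_bp <- c(0, 0.3, 0.7, 1) * length_bp
  round(stats::approx(knots_cm, knots_bp, xout = cm, rule = 2)$y)
}

#' Simulate a structured genotype panel
#'
#' Draws a biallelic dosage matrix under a Balding-Nichols model:
#' subpopulation allele frequencies are Beta-distributed around an ancestral
#' frequency with dispersion set by `fst`. Within each subpopulation a pool
#' of founder haplotypes is generated with allele correlation decaying
#' exponentially along the genetic map at scale `ld_decay_cm` (a latent
#' Gaussian AR(1) copula, so marginal frequencies are respected), and every
#' accession haplotype is a mosaic of those founders with crossovers at 1 per
#' 100 cM. This yields map-consistent linkage disequilibrium that decays with
#' genetic distance — the property the downstream hotspot confidence-interval
#' logic relies on.
#'
#' Missing calls are missing-completely-at-random with per-marker missingness
#' capped at `missing_rate`; markers whose observed minor-allele frequency
#' falls below `maf_floor` are redrawn so the panel respects the floor.
#' Markers are inserted at every planted-QTL genetic position.
#'
#' @param cfg A [sim_config()] object.
#' @return A `genotype_panel`: list with `dosages` (accession x marker matrix
#'   in `{0, 1, 2, NA}`), `map` (tibble `marker_id`, `chromosome`, `cm`,
#'   `bp`), `accessions` (tibble `accession_id`, `subpop`) and `chrom_info`
#'   (tibble `chromosome`, `length_cm`, `length_bp`, `centromere_cm`,
#'   `ld_decay_cm`).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_accessions
  chroms <- chromosome_names(cfg$n_chromosomes)

  acc_ids <- sprintf("acc%03d", seq_len(n))
  subpop <- sort(rep_len(seq_len(cfg$n_subpops), n))
  accessions <- tibble::tibble(accession_id = acc_ids,
                               subpop = paste0("SP", subpop))

  dos_list <- vector("list", cfg$n_chromosomes)
  map_list <- vector("list", cfg$n_chromosomes)
  K <- cfg$founders_per_subpop

  for (c_i in seq_len(cfg$n_chromosomes)) {
    M <- cfg$markers_per_chrom[c_i]
    L <- cfg$map_length_cm[c_i]
    ld <- cfg$ld_decay_cm[c_i]
    pos <- sort(stats::runif(M, 0, L))
    if (!is.null(cfg$planted_qtls)) {
      pq <- cfg$planted_qtls[cfg$planted_qtls$chrom == chroms[c_i], ]
      for (p in unique(pq$cm)) pos[which.min(abs(pos - p))] <- p
      pos <- sort(pos)
    }
    d_cm <- diff(pos)

    p_anc <- stats::runif(M, 0.1, 0.9)
    # the finite founder pool itself contributes ~1/K of drift variance;
    # shrink the Balding-Nichols dispersion so total differentiation
    # matches the requested fst (see methods vignette)
    f_eff <- max((cfg$fst - 1 / K) / (1 - 1 / K), 1e-4)
    shp <- (1 - f_eff) / f_eff
    # subpop x marker allele frequencies (Balding-Nichols)
    freq <- matrix(stats::rbeta(cfg$n_subpops * M,
                                rep(p_anc, each = cfg$n_subpops) * shp,
                                rep(1 - p_anc, each = cfg$n_subpops) * shp),
                   nrow = cfg$n_subpops)
    freq <- pmin(pmax(freq, 1e-4), 1 - 1e-4)

    # founder haplotypes: latent AR(1) thresholded at the subpop frequency
    r <- exp(-d_cm / ld)
    nf <- cfg$n_subpops * K
    z <- matrix(NA_real_, nf, M)
    z[, 1] <- stats::rnorm(nf)
    for (m in 2:M) {
      z[, m] <- r[m - 1] * z[, m - 1] +
        sqrt(1 - r[m - 1]^2) * stats::rnorm(nf)
    }
    fpop <- rep(seq_len(cfg$n_subpops), each = K)
    thr <- stats::qnorm(freq)              # subpop x marker
    founders <- (z < thr[fpop, , drop = FALSE]) * 1L

    # accession haplotypes as founder mosaics, 1 crossover per 100 cM
    H <- 2L * n
    hpop <- rep(subpop, each = 2L)
    p_switch <- 1 - exp(-d_cm / 100)
    fidx <- matrix(NA_integer_, H, M)
    fidx[, 1] <- sample.int(K, H, replace = TRUE)
    for (m in 2:M) {
      sw <- stats::runif(H) < p_switch[m - 1]
      fidx[, m] <- ifelse(sw, sample.int(K, H, replace = TRUE), fidx[, m - 1])
    }
    hap <- matrix(0L, H, M)
    for (m in seq_len(M)) {
      hap[, m] <- founders[cbind((hpop - 1L) * K + fidx[, m], m)]
    }
    dos <- hap[seq(1, H, 2), , drop = FALSE] + hap[seq(2, H, 2), , drop = FALSE]

    # MCAR missing calls, per-marker count capped at the configured rate
    if (cfg$missing_rate > 0) {
      cap <- floor(n * cfg$missing_rate)
      for (m in seq_len(M)) {
        nm <- min(stats::rbinom(1, n, cfg$missing_rate), cap)
        if (nm > 0) dos[sample.int(n, nm), m] <- NA_integer_
      }
    }

    # enforce the observed minor-allele-frequency floor
    if (cfg$maf_floor > 0) {
      maf <- function(v) {
        f <- mean(v, na.rm = TRUE) / 2
        min(f, 1 - f)
      }
      for (m in seq_len(M)) {
        tries <- 0
        while (maf(dos[, m]) < cfg$maf_floor && tries < 50) {
          keep_na <- is.na(dos[, m])
          f2 <- stats::rbeta(cfg$n_subpops, 0.5 * shp, 0.5 * shp)
          f2 <- pmin(pmax(f2, 0.15), 0.85)
          dos[, m] <- stats::rbinom(n, 2, f2[subpop])
          dos[keep_na, m] <- NA_integer_
          tries <- tries + 1
        }
      }
    }

    mids <- sprintf("%s_m%04d", chroms[c_i], seq_len(M))
    colnames(dos) <- mids
    dos_list[[c_i]] <- dos
    map_list[[c_i]] <- tibble::tibble(
      marker_id = mids, chromosome = chroms[c_i], cm = pos,
      bp = bp_from_cm(pos, L, cfg$chrom_length_bp[c_i],
                      cfg$centromere_cm[c_i]))
  }

  dosages <- do.call(cbind, dos_list)
  rownames(dosages) <- acc_ids
  structure(list(
    dosages = dosages,
    map = dplyr::bind_rows(map_list),
    accessions = accessions,
    chrom_info = tibble::tibble(
      chromosome = chroms,
      length_cm = cfg$map_length_cm,
      length_bp = cfg$chrom_length_bp,
      centromere_cm = cfg$centromere_cm,
      ld_decay_cm = cfg$ld_decay_cm)
  ), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d accessions x %d markers on %d chromosomes\n",
              nrow(x$dosages), ncol(x$dosages), nrow(x$chrom_info)))
  cat(sprintf("  missingness %.1f%%, %d subpopulations\n",
              100 * mean(is.na(x$dosages)),
              dplyr::n_distinct(x$accessions$subpop)))
  invisible(x)
}

# mean-imputed, optionally centered dosage matrix
impute_dosages <- function(dosages, center = FALSE) {
  cm <- colMeans(dosages, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  idx <- which(is.na(dosages))
  if (length(idx)) dosages[idx] <- cm[(idx - 1) %/% nrow(dosages) + 1]
  if (center) dosages <- sweep(dosages, 2, cm)
  dosages
}

# genetic value for one trait: planted-QTL part plus an orthogonalized
# polygenic remainder, with realized variances held on target
genetic_values_for_trait <- function(panel, cfg, trait) {
  X <- impute_dosages(panel$dosages, center = TRUE)
  n <- nrow(X)
  h2 <- cfg$h2_targets[[trait]]
  vp <- 1 + cfg$sigma2_res
  g_qtl <- rep(0, n)
  qtl_rows <- NULL
  if (!is.null(cfg$planted_qtls)) {
    pq <- cfg$planted_qtls[cfg$planted_qtls$trait == trait, , drop = FALSE]
    if (nrow(pq)) {
      idx <- purrr::map_int(seq_len(nrow(pq)), function(i) {
        j <- which(panel$map$chromosome == pq$chrom[i] &
                     abs(panel$map$cm - pq$cm[i]) < 1e-6)
        if (!length(j)) {
          stop(sprintf("planted QTL at %s:%.3f cM has no marker",
                       pq$chrom[i], pq$cm[i]))
        }
        j[1]
      })
      beta <- sqrt(pq$effect * vp / apply(X[, idx, drop = FALSE], 2, stats::var))
      g_qtl <- as.numeric(X[, idx, drop = FALSE] %*% beta)
      qtl_rows <- tibble::tibble(
        chrom = pq$chrom, cm = pq$cm, trait = trait, effect = pq$effect,
        marker_id = panel$map$marker_id[idx], beta = beta)
    }
  }
  var_poly <- h2 - sum(if (is.null(qtl_rows)) 0 else qtl_rows$effect) * vp
  u <- as.numeric(X %*% stats::rnorm(ncol(X)))
  if (stats::var(g_qtl) > 0) u <- stats::residuals(stats::lm(u ~ g_qtl))
  u <- scale_to_var(u, max(var_poly, 0))
  list(g = g_qtl + u, qtl = qtl_rows)
}

# augmented-design field layout for one year
field_layout <- function(acc_ids, check_ids, check_ratio) {
  n_test <- length(acc_ids)
  n_check <- round(n_test * check_ratio)
  entries <- sample(acc_ids)                       # randomized test order
  is_check <- logical(n_test + n_check)
  out <- character(n_test + n_check)
  if (n_check > 0) {
    check_pos <- round(seq(1, n_test + n_check, length.out = n_check))
    is_check[check_pos] <- TRUE
    out[check_pos] <- rep_len(check_ids, n_check)
  }
  out[!is_check] <- entries
  N <- length(out)
  n_rows <- ceiling(sqrt(N))
  tibble::tibble(
    accession_id = out, is_check = is_check,
    row = ((seq_len(N) - 1L) %% n_rows) + 1L,
    column = ((seq_len(N) - 1L) %/% n_rows) + 1L)
}

#' Simulate multi-year augmented-design phenotypes
#'
#' Generates plot-level records per year under
#' `y = mu + year + sum(QTL effects) + polygenic + genotype-by-year + row +
#' column + residual`. Variance components follow the `sim_config` targets:
#' the core variance `sigma2_G + sigma2_E + sigma2_GE` is 1 with
#' `sigma2_G = h2_target`, and realized draws are rescaled so components hit
#' their targets exactly (exact-variance conditioning; see the methods
#' vignette). The field layout is an augmented design: each accession once
#' per year plus two designated check accessions replicated at
#' `check_ratio`, assigned to a row-by-column grid.
#'
#' @param panel A `genotype_panel` from [simulate_genotypes()].
#' @param cfg The [sim_config()] that produced the panel.
#' @return A list with `phenotypes` (tibble `plot_id`, `accession_id`,
#'   `year`, `row`, `column`, `is_check`, `trait`, `value`) and
#'   `ground_truth` (planted QTLs with realized allele effects,
#'   per-trait variance components, accession genetic values, and
#'   subpopulation assignments).
#' @export
simulate_phenotypes <- function(panel, cfg) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  traits <- names(cfg$h2_targets)
  acc_ids <- panel$accessions$accession_id
  n <- length(acc_ids)
  check_ids <- sort(acc_ids)[1:2]

  layouts <- purrr::map(cfg$years, function(y) {
    dplyr::mutate(field_layout(acc_ids, check_ids, cfg$check_ratio),
                  year = y,
                  plot_id = sprintf("Y%s_P%03d", y, dplyr::row_number()))
  })
  names(layouts) <- cfg$years
  ny <- length(cfg$years)

  pheno <- list()
  truth_qtl <- list()
  truth_vc <- list()
  truth_g <- list()
  for (tr in traits) {
    h2 <- cfg$h2_targets[[tr]]
    s2_E <- cfg$e_share * (1 - h2)
    s2_GE <- (1 - cfg$e_share) * (1 - h2)
    gv <- genetic_values_for_trait(panel, cfg, tr)
    g <- stats::setNames(gv$g, acc_ids)
    year_eff <- stats::setNames(scale_to_var(stats::rnorm(ny), s2_E), cfg$years)
    ge <- matrix(stats::rnorm(n * ny), n, ny,
                 dimnames = list(acc_ids, cfg$years))
    ge <- matrix(scale_to_var(as.numeric(ge), s2_GE), n, ny,
                 dimnames = list(acc_ids, cfg$years))
    rows_tr <- purrr::map(cfg$years, function(y) {
      lay <- layouts[[y]]
      re <- stats::rnorm(max(lay$row), 0, sqrt(cfg$sigma2_row))
      ce <- stats::rnorm(max(lay$column), 0, sqrt(cfg$sigma2_col))
      dplyr::mutate(
        lay, trait = tr,
        value = 10 + year_eff[[y]] + g[.data$accession_id] +
          ge[cbind(.data$accession_id, y)] + re[.data$row] + ce[.data$column] +
          stats::rnorm(dplyr::n(), 0, sqrt(cfg$sigma2_res)))
    })
    pheno[[tr]] <- dplyr::bind_rows(rows_tr)
    truth_qtl[[tr]] <- gv$qtl
    truth_vc[[tr]] <- tibble::tibble(
      trait = tr, sigma2_G = h2, sigma2_E = s2_E, sigma2_GE = s2_GE,
      sigma2_res = cfg$sigma2_res, h2 = h2)
    truth_g[[tr]] <- tibble::tibble(accession_id = acc_ids, trait = tr,
                                    g = unname(g))
  }

  phenotypes <- dplyr::select(
    dplyr::bind_rows(pheno),
    "plot_id", "accession_id", "year", "row", "column", "is_check",
    "trait", "value")
  ground_truth <- list(
    qtl = dplyr::bind_rows(truth_qtl),
    variance_components = dplyr::bind_rows(truth_vc),
    genetic_values = dplyr::bind_rows(truth_g),
    subpops = panel$accessions,
    check_ids = check_ids)
  list(phenotypes = phenotypes, ground_truth = ground_truth)
}

#' Simulate four-band canopy reflectance per plot
#'
#' Each accession receives a latent canopy-cover variable with heritability
#' `h2_canopy`; planted QTLs for the trait `"canopy"` in the configuration
#' contribute their stated variance fractions to its genetic part, so
#' vegetation indices computed from these spectra are heritable and
#' GWAS-mappable. Band reflectances are a deterministic linear soil-to-
#' vegetation mixture of the canopy variable in the four camera bands
#' (green 550, red 660, red-edge 735, NIR 790 nm): NIR increases and red
#' decreases with canopy, so NDVI is strictly increasing in canopy cover.
#' The postanthesis stage shifts the canopy distribution downward
#' (senescence).
#'
#' @param panel A `genotype_panel`.
#' @param truth Ground truth from [simulate_phenotypes()] (used for
#'   subpopulation bookkeeping; canopy genetics are drawn from the panel).
#' @param stage `"anthesis"` or `"postanthesis"`.
#' @param cfg The [sim_config()]; supplies planted canopy QTLs and the seed.
#' @param h2_canopy Heritability of the latent canopy variable.
#' @return Tibble with `plot_id`, `accession_id`, `stage`, the four band
#'   reflectances in `[0, 1]`, and the latent `canopy` (simulation truth,
#'   kept for validation).
#' @export
simulate_reflectance <- function(panel, truth, stage = c("anthesis", "postanthesis"),
                                 cfg = NULL, h2_canopy = 0.5) {
  stage <- match.arg(stage)
  acc_ids <- panel$accessions$accession_id
  n <- length(acc_ids)
  seed <- if (!is.null(cfg)) cfg$seed else 1L
  set.seed(seed + 2L + (stage == "postanthesis"))

  g_qtl <- rep(0, n)
  if (!is.null(cfg) && !is.null(cfg$planted_qtls)) {
    pq <- cfg$planted_qtls[cfg$planted_qtls$trait == "canopy", , drop = FALSE]
    if (nrow(pq)) {
      X <- impute_dosages(panel$dosages, center = TRUE)
      for (i in seq_len(nrow(pq))) {
        j <- which(panel$map$chromosome == pq$chrom[i] &
                     abs(panel$map$cm - pq$cm[i]) < 1e-6)[1]
        if (is.na(j)) stop("planted canopy QTL has no marker")
        x <- X[, j]
        g_qtl <- g_qtl + x * sqrt(pq$effect[i] / stats::var(x))
      }
    }
  }
  var_poly <- max(h2_canopy - stats::var(g_qtl), 0)
  u <- scale_to_var(stats::rnorm(n), var_poly)
  e <- scale_to_var(stats::rnorm(n), 1 - h2_canopy)
  latent <- g_qtl + u + e
  shift <- if (stage == "anthesis") 1.0 else -0.5
  canopy <- stats::plogis(latent + shift)

  soil <- c(green = 0.16, red = 0.22, rededge = 0.26, nir = 0.30)
  veg <- c(green = 0.08, red = 0.04, rededge = 0.35, nir = 0.55)
  tibble::tibble(
    plot_id = sprintf("PL_%s", acc_ids),
    accession_id = acc_ids,
    stage = stage,
    green = soil[["green"]] + canopy * (veg[["green"]] - soil[["green"]]),
    red = soil[["red"]] + canopy * (veg[["red"]] - soil[["red"]]),
    rededge = soil[["rededge"]] + canopy * (veg[["rededge"]] - soil[["rededge"]]),
    nir = soil[["nir"]] + canopy * (veg[["nir"]] - soil[["nir"]]),
    canopy = canopy)
}

#' Write simulation ground truth as JSON
#'
#' @param truth Ground-truth list from [simulate_phenotypes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
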