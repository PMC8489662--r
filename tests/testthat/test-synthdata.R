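test_that("the generator is deterministic given a seed", {
  cfg <- tiny_cfg(seed = 7L)
  p1 <- simulate_genotypes(cfg)
  p2 <- simulate_genotypes(cfg)
  expect_identical(p1$dosages, p2$dosages)
  expect_identical(p1$map, p2$map)
  ph1 <- simulate_phenotypes(p1, cfg)
  ph2 <- simulate_phenotypes(p2, cfg)
  expect_identical(ph1$phenotypes, ph2$phenotypes)
  r1 <- simulate_reflectance(p1, ph1$ground_truth, "anthesis", cfg)
  r2 <- simulate_reflectance(p2, ph2$ground_truth, "anthesis", cfg)
  expect_identical(r1, r2)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(fst = 0), "fst")
  expect_error(sim_config(fst = 1.2), "fst")
  expect_error(sim_config(n_accessions = 0), "dimensions")
  expect_error(sim_config(missing_rate = 0.4), "missing_rate")
  expect_error(sim_config(centromere_cm = 200, map_length_cm = 160),
               "centromere")
  expect_error(
    sim_config(h2_targets = c(yield = 0.2),
               planted_qtls = data.frame(chrom = "1A", cm = 10,
                                         trait = "yield", effect = 0.5)),
    "exceeds")
})

test_that("differentiation tracks fst: Weir-Cockerham recovery and the no-structure limit", {
  cfg <- tiny_cfg(n_accessions = 1000, n_subpops = 2, fst = 0.2,
                  markers_per_chrom = 150, missing_rate = 0,
                  maf_floor = 0.01, seed = 11L)
  p <- simulate_genotypes(cfg)
  est <- wc_fst(p$dosages, p$accessions$subpop)
  expect_gt(est, 0.15)
  expect_lt(est, 0.25)

  # near-zero fst (large founder pool so pool drift is negligible) gives
  # far weaker subpopulation frequency differences
  freq_gap <- function(fst) {
    cfg0 <- tiny_cfg(n_accessions = 400, n_subpops = 2, fst = fst,
                     markers_per_chrom = 120, missing_rate = 0,
                     maf_floor = 0.01, founders_per_subpop = 200, seed = 13L)
    p0 <- simulate_genotypes(cfg0)
    sp <- split(seq_len(400), p0$accessions$subpop)
    f1 <- colMeans(p0$dosages[sp[[1]], ], na.rm = TRUE) / 2
    f2 <- colMeans(p0$dosages[sp[[2]], ], na.rm = TRUE) / 2
    mean(abs(f1 - f2))
  }
  gap_lo <- freq_gap(0.01)
  gap_hi <- freq_gap(0.4)
  expect_lt(gap_lo, 0.1)
  expect_lt(gap_lo, gap_hi / 3)
})

test_that("markers respect the MAF floor and missingness cap", {
  cfg <- tiny_cfg(missing_rate = 0.1, maf_floor = 0.05, seed = 3L)
  p <- simulate_genotypes(cfg)
  freq <- colMeans(p$dosages, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  expect_true(all(maf >= 0.05))
  miss <- colMeans(is.na(p$dosages))
  expect_true(all(miss <= 0.1 + 1e-12))
  expect_true(all(p$dosages %in% c(0L, 1L, 2L, NA)))
})

test_that("linkage disequilibrium decays with genetic distance", {
  cfg <- tiny_cfg(n_accessions = 300, markers_per_chrom = 120,
                  ld_decay_cm = 5, missing_rate = 0, seed = 5L)
  p <- simulate_genotypes(cfg)
  m1 <- p$map[p$map$chromosome == "chr1", ]
  X <- p$dosages[, m1$marker_id]
  r2_at <- function(lo, hi) {
    pairs <- which(outer(m1$cm, m1$cm, function(a, b) {
      d <- b - a
      d > lo & d <= hi
    }), arr.ind = TRUE)
    pairs <- pairs[seq_len(min(400, nrow(pairs))), , drop = FALSE]
    mean(vapply(seq_len(nrow(pairs)), function(k) {
      suppressWarnings(stats::cor(X[, pairs[k, 1]], X[, pairs[k, 2]]))^2
    }, numeric(1)), na.rm = TRUE)
  }
  close_r2 <- r2_at(0, 2)
  far_r2 <- r2_at(30, 60)
  expect_gt(close_r2, 3 * far_r2)
})

test_that("the physical map is monotone and centromere-aware", {
  cfg <- tiny_cfg(seed = 2L)
  p <- simulate_genotypes(cfg)
  for (ch in unique(p$map$chromosome)) {
    m <- p$map[p$map$chromosome == ch, ]
    expect_true(all(diff(m$cm) >= 0))
    expect_true(all(diff(m$bp) >= 0))
  }
  # bp per cM is larger inside the pericentromeric window than outside
  m <- p$map[p$map$chromosome == "chr1", ]
  cen <- p$chrom_info$centromere_cm[1]
  rate <- diff(m$bp) / pmax(diff(m$cm), 1e-9)
  mid <- (m$cm[-1] + m$cm[-nrow(m)]) / 2
  inside <- abs(mid - cen) < 0.04 * p$chrom_info$length_cm[1]
  stopifnot(sum(inside) >= 2)   # holds at this seed and density
  expect_gt(stats::median(rate[inside]), stats::median(rate[!inside]))
})

test_that("phenotype simulation hits its variance targets and layout contract", {
  cfg <- tiny_cfg(n_accessions = 250, h2_targets = c(yield = 0.6),
                  years = c("2016", "2017", "2018"), seed = 9L)
  p <- simulate_genotypes(cfg)
  sp <- simulate_phenotypes(p, cfg)
  tab <- sp$phenotypes

  # layout: every plot has a row, column and check label; 1:4 ratio
  expect_true(all(c("row", "column", "is_check") %in% names(tab)))
  one_year <- dplyr::filter(tab, year == "2016", trait == "yield")
  expect_equal(sum(one_year$is_check),
               round(cfg$check_ratio * cfg$n_accessions))
  expect_false(any(duplicated(one_year[, c("row", "column")])))

  # realized genetic variance matches sigma2_G within 10%
  g <- sp$ground_truth$genetic_values$g
  expect_lt(abs(stats::var(g) - 0.6) / 0.6, 0.1)

  # checks appear in every year
  checks <- dplyr::filter(tab, is_check)
  expect_setequal(unique(checks$year), cfg$years)
})

test_that("noise-free and noise-only limits behave", {
  # residual-only trait: realized heritability near zero
  cfg0 <- tiny_cfg(n_accessions = 150, h2_targets = c(flat = 0),
                   years = c("2016", "2017"), seed = 21L)
  p0 <- simulate_genotypes(cfg0)
  sp0 <- simulate_phenotypes(p0, cfg0)
  f0 <- fit_mixed_model(sp0$phenotypes, "flat")
  expect_lt(f0$sigma2_G / (f0$sigma2_G + f0$sigma2_res + f0$sigma2_E +
                             f0$sigma2_GE + 1e-12), 0.05)

  # h2 = 1 with no residual: accession means reproduce genetic values
  cfg1 <- tiny_cfg(n_accessions = 150, h2_targets = c(pure = 1),
                   sigma2_res = 1e-6, sigma2_row = 0, sigma2_col = 0,
                   years = c("2016", "2017"), seed = 22L)
  p1 <- simulate_genotypes(cfg1)
  sp1 <- simulate_phenotypes(p1, cfg1)
  am <- dplyr::filter(accession_means(sp1$phenotypes), environment == "mean")
  tr <- sp1$ground_truth$genetic_values
  d <- dplyr::inner_join(am, tr, by = "accession_id")
  expect_gt(stats::cor(d$value, d$g), 0.999)
})

test_that("planted QTLs must coincide with markers", {
  cfg <- tiny_cfg(planted_qtls = data.frame(chrom = "chr1", cm = 50,
                                            trait = "yield", effect = 0.1),
                  seed = 4L)
  p <- simulate_genotypes(cfg)
  expect_true(any(p$map$chromosome == "chr1" & abs(p$map$cm - 50) < 1e-9))
  sp <- simulate_phenotypes(p, cfg)
  expect_identical(nrow(sp$ground_truth$qtl), 1L)
  expect_identical(
    sp$ground_truth$qtl$marker_id,
    p$map$marker_id[p$map$chromosome == "chr1" & abs(p$map$cm - 50) < 1e-9])

  # a panel lacking the planted position fails loudly
  cfg2 <- tiny_cfg(seed = 4L)
  p2 <- simulate_genotypes(cfg2)
  cfg2$planted_qtls <- tibble::tibble(chrom = "chr1", cm = 50.123456,
                                      trait = "yield", effect = 0.1)
  expect_error(simulate_phenotypes(p2, cfg2), "no marker")
})

test_that("reflectance is a monotone soil-to-canopy mixture", {
  cfg <- tiny_cfg(seed = 6L)
  p <- simulate_genotypes(cfg)
  sp <- simulate_phenotypes(p, cfg)
  refl <- simulate_reflectance(p, sp$ground_truth, "anthesis", cfg)
  expect_true(all(refl[, c("green", "red", "rededge", "nir")] >= 0 &
                    refl[, c("green", "red", "rededge", "nir")] <= 1))
  ndvi <- (refl$nir - refl$red) / (refl$nir + refl$red)
  ord <- order(refl$canopy)
  expect_true(all(diff(ndvi[ord]) > 0))

  post <- simulate_reflectance(p, sp$ground_truth, "postanthesis", cfg)
  expect_lt(mean(post$canopy), mean(refl$canopy))
  expect_error(simulate_reflectance(p, sp$ground_truth, "booting", cfg))

  # bands are exactly linear in canopy, so the canopy = 0 limit is the
  # bare-soil spectrum (intercept of the band-on-canopy regression)
  soil <- c(green = 0.16, red = 0.22, rededge = 0.26, nir = 0.30)
  for (b in names(soil)) {
    fit <- stats::lm(refl[[b]] ~ refl$canopy)
    expect_equal(unname(stats::coef(fit)[1]), soil[[b]], tolerance = 1e-9)
  }
  expect_lt(stats::coef(stats::lm(refl$red ~ refl$canopy))[2], 0)
  expect_gt(stats::coef(stats::lm(refl$nir ~ refl$canopy))[2], 0)
})
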