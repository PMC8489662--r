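# Small simulation configurations and independent oracles shared by tests.

tiny_cfg <- function(...) {
  defaults <- list(n_accessions = 60, n_subpops = 3, fst = 0.2,
                   n_chromosomes = 2, markers_per_chrom = 60,
                   map_length_cm = 100, chrom_length_bp = 4e8,
                   ld_decay_cm = 5, h2_targets = c(yield = 0.6),
                   years = c("2016", "2017"), missing_rate = 0.05,
                   seed = 7L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# hand-built 4-accession panel used for exact-arithmetic checks
toy_panel <- function(dosages = NULL) {
  if (is.null(dosages)) {
    dosages <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L,
                        2L, 1L, 0L, 1L, 2L, 0L,
                        1L, 1L, 1L, 2L, 0L, 1L,
                        0L, 2L, 1L, 0L, 1L, 2L),
                      nrow = 4, byrow = TRUE)
  }
  rownames(dosages) <- paste0("a", seq_len(nrow(dosages)))
  colnames(dosages) <- paste0("m", seq_len(ncol(dosages)))
  map <- tibble::tibble(marker_id = colnames(dosages), chromosome = "chr1",
                        cm = seq_len(ncol(dosages)) * 10,
                        bp = seq_len(ncol(dosages)) * 1e6)
  genotype_panel(dosages, map)
}

# Weir-Cockerham multi-population theta (ratio of averages), an
# estimator independent of the generator's Balding-Nichols construction
wc_fst <- function(dos, pop) {
  pops <- split(seq_len(nrow(dos)), pop)
  r <- length(pops)
  num <- den <- 0
  for (m in seq_len(ncol(dos))) {
    ni <- sapply(pops, function(i) sum(!is.na(dos[i, m])))
    pi <- sapply(pops, function(i) mean(dos[i, m], na.rm = TRUE) / 2)
    hi <- sapply(pops, function(i) mean(dos[i, m] == 1, na.rm = TRUE))
    nbar <- mean(ni)
    pbar <- sum(ni * pi) / (r * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# independent step-by-step vegetation-index arithmetic (scalar, written
# as explicit intermediate quantities rather than the registry algebra)
oracle_vi <- function(index, g, r, re, n) {
  switch(index,
    NDVI = {
      num <- n - r; den <- n + r
      num / den
    },
    RDVI = {
      num <- n - r
      num / sqrt(n + r)
    },
    MSAVI = {
      t1 <- 2 * n + 1
      disc <- t1 * t1 - 8 * (n - r)
      (t1 - sqrt(disc)) / 2
    },
    MTVI2 = {
      num <- 1.5 * (1.2 * (n - g) - 2.5 * (r - g))
      t1 <- (2 * n + 1)^2
      t2 <- 6 * n - 5 * sqrt(r)
      num / sqrt(t1 - t2 - 0.5)
    },
    GNDVI = {
      (n - g) / (n + g)
    },
    TCARI_OSAVI = {
      tcari <- 3 * ((re - r) - 0.2 * (re - g) * (re / r))
      osavi <- 1.16 * (n - r) / (n + r + 0.16)
      tcari / osavi
    },
    stop("unknown index"))
}

# expected overview-index bin value by adaptive quadrature of the
# Gaussian density over the bin (independent of the closed-form pnorm path)
oracle_bin_mass <- function(center, mu, s, bin = 1) {
  sum(vapply(seq_along(mu), function(i) {
    stats::integrate(function(x) stats::dnorm(x, mu[i], s[i]),
                     center - bin / 2, center + bin / 2,
                     rel.tol = 1e-10)$value
  }, numeric(1)))
}

# minimal single-year phenotype table on an n x 1 grid
flat_pheno <- function(values, trait = "tr", year = "2016") {
  n <- length(values)
  tibble::tibble(
    plot_id = sprintf("Y%s_P%03d", year, seq_len(n)),
    accession_id = names(values) %||% sprintf("acc%03d", seq_len(n)),
    year = year, row = seq_len(n), column = 1L, is_check = FALSE,
    trait = trait, value = unname(values))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
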