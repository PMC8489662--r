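test_that("LD profile and MTA confidence intervals follow the Gaussian construction", {
  ld <- ld_profile(c("1A", "2B"), c(3.92, 10))
  expect_equal(ld$s_cm, c(1, 10 / 3.92), tolerance = 1e-12)
  expect_equal(ld$s_cm[2], 2.551, tolerance = 1e-3)
  mtas <- tibble::tibble(chromosome = c("1A", "1A"), cm = c(50, 1))
  ci <- mta_ci(mtas, ld_profile("1A", 10),
               map_lengths = tibble::tibble(chromosome = "1A",
                                            length_cm = 100))
  expect_equal(ci$lower_cm, c(45, 0))     # boundary clipped at 0
  expect_equal(ci$upper_cm, c(55, 6))
  expect_error(mta_ci(tibble::tibble(chromosome = "9Z", cm = 1),
                      ld_profile("1A", 10)), "9Z")
})

test_that("overview index conserves probability mass and is linear in MTAs", {
  ld <- ld_profile("1A", 3.92 * 2)       # s = 2
  ml <- tibble::tibble(chromosome = "1A", length_cm = 150)
  one <- tibble::tibble(chromosome = "1A", cm = 75, trait = "t",
                        environment = "e")
  prof <- overview_index(one, ld, ml, nb_experiments = 1)
  # single interior MTA, nbE = 1: total mass is 1 minus edge truncation
  edge <- 2 * pnorm(-75 / 2)
  expect_equal(sum(prof$u), 1, tolerance = max(edge, 1e-9))
  # two co-located MTAs double the index pointwise
  two <- dplyr::bind_rows(one, one)
  prof2 <- overview_index(two, ld, ml, nb_experiments = 1)
  expect_equal(prof2$u, 2 * prof$u, tolerance = 1e-12)
  # dividing by nbE scales it back
  prof2e <- overview_index(two, ld, ml, nb_experiments = 2)
  expect_equal(prof2e$u, prof$u, tolerance = 1e-12)
})

test_that("the map-wide mean of the index equals the closed-form U", {
  # interior MTAs far from edges: mean(u) = nbQTL / (nbE * L) to 1e-9
  ld <- ld_profile(c("1A", "2A"), c(6, 10))
  ml <- tibble::tibble(chromosome = c("1A", "2A"), length_cm = c(120, 80))
  mtas <- tibble::tibble(chromosome = c("1A", "1A", "2A"),
                         cm = c(50, 61.3, 40),
                         trait = "t", environment = c("a", "b", "a"))
  prof <- overview_index(mtas, ld, ml, nb_experiments = 2)
  U <- 3 / (2 * (120 + 80))
  expect_equal(mean(prof$u), U, tolerance = 1e-9)
  expect_equal(attr(prof, "mean_threshold"), mean(prof$u))
  expect_equal(attr(prof, "high_threshold"), 5 * mean(prof$u))
})

test_that("bin values agree with a numerical-quadrature oracle", {
  ld <- ld_profile("3B", 3.92 * 2)       # s = 2 exactly
  ml <- tibble::tibble(chromosome = "3B", length_cm = 150)
  mtas <- tibble::tibble(chromosome = "3B",
                         cm = c(30, 31.5, 70, 70, 110.25),
                         trait = "t",
                         environment = rep(c("y1", "y2"), c(3, 2)))
  prof <- overview_index(mtas, ld, ml, nb_experiments = 2)
  for (probe in c(30.5, 70.5, 109.5)) {
    want <- oracle_bin_mass(probe, mtas$cm, rep(2, 5)) / 2
    got <- prof$u[abs(prof$cm - probe) < 1e-9]
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("peak calling finds local maxima above tier thresholds", {
  ld <- ld_profile("1A", 4)
  ml <- tibble::tibble(chromosome = "1A", length_cm = 100)
  # flat (empty) profile: no peaks anywhere
  empty <- overview_index(tibble::tibble(chromosome = character(),
                                         cm = numeric(), trait = character(),
                                         environment = character()),
                          ld, ml, nb_experiments = 1)
  expect_identical(nrow(call_peaks(empty)), 0L)

  # single bump: exactly one peak at the mode bin
  one <- overview_index(tibble::tibble(chromosome = "1A", cm = 50.5,
                                       trait = "t", environment = "e"),
                        ld, ml, nb_experiments = 1)
  pk <- call_peaks(one)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$cm, 50.5)
  expect_identical(pk$tier, "high")

  # three bumps, one diluted below the mean threshold: two peaks
  ld_wide <- ld_profile("1A", 12)
  mtas3 <- tibble::tibble(
    chromosome = "1A",
    cm = c(rep(20.5, 10), rep(60.5, 10), 90.5),
    trait = "t", environment = "e")
  prof3 <- overview_index(mtas3, ld_wide, ml, nb_experiments = 1)
  pk3 <- call_peaks(prof3, mean_mult = 1, high_mult = 5)
  expect_identical(nrow(pk3), 2L)
  expect_setequal(pk3$cm, c(20.5, 60.5))

  # the high tier is a subset of all called peaks
  expect_true(all(dplyr::filter(pk3, tier == "high")$cm %in% pk3$cm))
  expect_error(call_peaks(prof3[0, ]), "empty")
})

test_that("plateaus resolve to their midpoint bin deterministically", {
  prof <- tibble::tibble(chromosome = "1A", cm = seq(0.5, 9.5, 1),
                         u = c(0, 0, 1, 1, 1, 0, 0, 0, 0, 0))
  class(prof) <- c("overview_profile", class(prof))
  pk <- call_peaks(prof, mean_mult = 1, high_mult = 5)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$cm, 3.5)               # middle of the 3-bin plateau
})

test_that("physical intervals reproduce published flanking-marker arithmetic", {
  ref <- readr::read_csv(
    system.file("extdata", "published_hotspot_intervals.csv",
                package = "qtlhotspots"),
    show_col_types = FALSE)
  got <- physical_interval(ref$left_bp, ref$right_bp)
  expect_equal(got, ref$ci_mb)
  # the reversed-order row actually exercises the absolute value
  rev_row <- ref[ref$left_bp > ref$right_bp, ]
  expect_identical(nrow(rev_row), 1L)
  expect_equal(physical_interval(rev_row$left_bp, rev_row$right_bp), 4.5)
  expect_equal(physical_interval(5e6, 5e6), 0)
  # half-up rounding at the boundary
  expect_equal(physical_interval(0, 250000), 0.3)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(0.24999, 1), 0.2)
})

test_that("peak merging honors CI-window overlap and chromosome boundaries", {
  ld <- ld_profile(c("1A", "2A"), c(10, 10))
  map <- tibble::tibble(
    marker_id = sprintf("mk%02d", 1:20),
    chromosome = rep(c("1A", "2A"), each = 10),
    cm = rep(seq(5, 95, by = 10), 2),
    bp = rep(seq(5, 95, by = 10), 2) * 1e6)
  mtas <- tibble::tibble(
    chromosome = c("1A", "1A", "1A", "2A"),
    cm = c(40, 41, 70, 40),
    trait = c("t1", "t2", "t1", "t1"),
    environment = c("y1", "y2", "y1", "y1"),
    neglog10p = c(5, 6, 4, 5))

  # two peaks 1 cM apart with 10-cM windows merge into one hotspot
  peaks <- tibble::tibble(chromosome = "1A", cm = c(40.5, 41.5),
                          u = c(1, 0.9))
  hs <- merge_to_hotspots(peaks, mtas, ld, map)
  expect_identical(nrow(hs), 1L)
  expect_equal(hs$peak_cm, 40.5)
  expect_identical(hs$id, "QTL1A.1")
  expect_identical(hs$n_mtas, 2L)        # MTAs at 40, 41 inside [35.5, 46.5]
  expect_identical(hs$traits, "t1,t2")
  expect_identical(hs$n_environments, 2L)
  expect_equal(hs$max_neglog10p, 6)
  # flanking markers at/outside the window bounds
  expect_identical(hs$left_marker, "mk04")   # cm 35 <= 35.5
  expect_identical(hs$right_marker, "mk06")  # first marker at cm >= 46.5
  expect_equal(hs$ci_mb, physical_interval(hs$left_bp, hs$right_bp))

  # peaks on different chromosomes never merge
  peaks2 <- tibble::tibble(chromosome = c("1A", "2A"), cm = c(40.5, 40.5),
                           u = c(1, 1))
  hs2 <- merge_to_hotspots(peaks2, mtas, ld, map)
  expect_identical(nrow(hs2), 2L)
  expect_setequal(hs2$chromosome, c("1A", "2A"))

  # four peaks with one overlapping pair -> three hotspots
  peaks4 <- tibble::tibble(chromosome = "1A", cm = c(10.5, 40.5, 43.5, 70.5),
                           u = c(1, 1, 0.8, 0.7))
  mtas4 <- dplyr::bind_rows(
    mtas, tibble::tibble(chromosome = "1A", cm = 10, trait = "t1",
                         environment = "y1", neglog10p = 4.2))
  hs4 <- merge_to_hotspots(peaks4, mtas4, ld, map)
  expect_identical(nrow(hs4), 3L)
  expect_identical(hs4$id, c("QTL1A.1", "QTL1A.2", "QTL1A.3"))

  # a peak window with no MTA inside is a contradiction
  lone <- tibble::tibble(chromosome = "2A", cm = 90.5, u = 1)
  expect_error(merge_to_hotspots(lone, mtas, ld, map), "no MTA")
})

test_that("exclusion rules drop centromeric, oversized and single-year hotspots", {
  mk_hs <- function(id, chrom, l, r, ci_mb, envs, traits) {
    tibble::tibble(id = id, chromosome = chrom, left_cm = l, peak_cm = (l + r) / 2,
                   right_cm = r, n_mtas = 3L, max_neglog10p = 5,
                   n_environments = envs, n_traits = traits,
                   traits = "t", environments = "e",
                   left_marker = "a", left_bp = 1e6, right_marker = "b",
                   right_bp = 1e6 + ci_mb * 1e6, ci_mb = ci_mb,
                   member_mtas = list(tibble::tibble()))
  }
  hs <- dplyr::bind_rows(
    mk_hs("QTL1A.1", "1A", 40, 60, 10, 2L, 2L),   # spans centromere at 50
    mk_hs("QTL1A.2", "1A", 80, 90, 36, 2L, 2L),   # CI 36 Mb > 35
    mk_hs("QTL2A.1", "2A", 10, 20, 10, 1L, 3L),   # single year
    mk_hs("QTL2A.2", "2A", 60, 70, 10, 2L, 1L),   # single trait
    mk_hs("QTL3A.1", "3A", 10, 20, 34.9, 2L, 2L)) # passes everything
  cen <- tibble::tibble(chromosome = c("1A", "2A", "3A"),
                        centromere_cm = c(50, 40, 50))
  kept <- filter_hotspots(hs, cen, max_ci_mb = 35, min_years = 2,
                          min_traits = 2)
  expect_identical(kept$id, "QTL3A.1")
  excl <- attr(kept, "excluded")
  expect_identical(nrow(excl), 4L)
  expect_match(excl$reason[excl$id == "QTL1A.1"], "centromere")
  expect_match(excl$reason[excl$id == "QTL1A.2"], "ci_gt_max")
  expect_match(excl$reason[excl$id == "QTL2A.1"], "single_year")
  expect_match(excl$reason[excl$id == "QTL2A.2"], "few_traits")
  # boundary: 35.0 Mb is retained, 36 dropped
  expect_false("QTL1A.2" %in% kept$id)
  # missing centromere entry is an error
  expect_error(filter_hotspots(hs, cen[1:2, ]), "3A")
})

test_that("hotspot BED export uses 0-based half-open physical intervals", {
  hs <- tibble::tibble(id = "QTL1A.1", chromosome = "1A",
                       left_bp = 7294564, right_bp = 9579957)
  path <- withr::local_tempfile(fileext = ".bed")
  hotspots_to_bed(hs, path)
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                         show_col_types = FALSE)
  expect_equal(bed$start, 7294563)
  expect_equal(bed$end, 9579957)
})
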