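#' LD-decay confidence-interval profiles per chromosome
#'
#' Each marker-trait association is smeared by a Gaussian whose 95%
#' interval equals the chromosome's linkage-disequilibrium decay distance
#' `CI`, so its standard deviation is `S = CI / 3.92` (3.92 being the
#' width of the central 95% of a standard normal).
#'
#' @param chromosome Character vector of chromosome names.
#' @param ci_cm LD-decay distance per chromosome (cM), used as the 95% CI.
#' @return Tibble `chromosome`, `ci_cm`, `s_cm` with `s_cm = ci_cm / 3.92`.
#' @export
#' @examples
#' ld_profile("1A", 3.92)  # s_cm = 1
ld_profile <- function(chromosome, ci_cm) {
  stopifnot(all(ci_cm > 0))
  tibble::tibble(chromosome = as.character(chromosome), ci_cm = ci_cm,
                 s_cm = ci_cm / 3.92)
}

#' Confidence intervals for marker-trait associations
#'
#' @param mtas MTA table with `chromosome` and `cm`.
#' @param ld LD profile from [ld_profile()] (or tibble with `chromosome`,
#'   `ci_cm`).
#' @param map_lengths Optional tibble `chromosome`, `length_cm` used to
#'   clip the bounds to the map.
#' @return The MTA rows with `s_cm`, `lower_cm`, `upper_cm` appended;
#'   bounds are `cm +- ci_cm / 2`, clipped to `[0, length_cm]`.
#' @export
mta_ci <- function(mtas, ld, map_lengths = NULL) {
  mtas <- tibble::as_tibble(mtas)
  ld <- normalize_ld(ld)
  missing_chr <- setdiff(unique(mtas$chromosome), ld$chromosome)
  if (length(missing_chr)) {
    stop("no LD-decay entry for chromosome(s): ",
         paste(missing_chr, collapse = ", "))
  }
  out <- dplyr::left_join(mtas, ld[, c("chromosome", "ci_cm", "s_cm")],
                          by = "chromosome")
  out <- dplyr::mutate(out,
                       lower_cm = pmax(.data$cm - .data$ci_cm / 2, 0),
                       upper_cm = .data$cm + .data$ci_cm / 2)
  if (!is.null(map_lengths)) {
    ml <- tibble::as_tibble(map_lengths)
    out <- dplyr::left_join(out, ml[, c("chromosome", "length_cm")],
                            by = "chromosome")
    out <- dplyr::mutate(out,
                         upper_cm = pmin(.data$upper_cm, .data$length_cm),
                         lower_cm = pmin(.data$lower_cm, .data$length_cm))
    out$length_cm <- NULL
  }
  out
}

normalize_ld <- function(ld) {
  ld <- tibble::as_tibble(ld)
  stopifnot(all(c("chromosome", "ci_cm") %in% names(ld)))
  if (!"s_cm" %in% names(ld)) ld$s_cm <- ld$ci_cm / 3.92
  ld
}

#' QTL overview index along the genetic map
#'
#' The per-cM density of MTA location probability. Each association on a
#' chromosome contributes, to the 1-cM bin centered at `x`, the Gaussian
#' probability mass `Phi((x + 1/2 - mu) / s) - Phi((x - 1/2 - mu) / s)`
#' where `mu` is its genetic position and `s` the chromosome's LD-decay
#' standard deviation ([ld_profile()]); the sum is divided by the number
#' of experiments `nbE`. Using bin mass rather than midpoint density makes
#' total mass exactly `nbQTL / nbE` up to edge truncation, and the map-wide
#' mean of the index equals the closed form `U = nbQTL / (nbE * L)` with
#' `L` the total map length.
#'
#' @param mtas MTA table (`chromosome`, `cm`, and `trait`/`environment`
#'   when `nb_experiments` is derived from the data).
#' @param ld LD profile ([ld_profile()]).
#' @param map_lengths Tibble `chromosome`, `length_cm` covering the whole
#'   map (chromosomes without MTAs included: they contribute zero bins to
#'   the map-wide mean).
#' @param nb_experiments Number of experiments `nbE`; defaults to the
#'   number of distinct `(trait, environment)` combinations in `mtas`.
#' @param bin_cm Bin width in cM (default 1, per-cM index).
#' @param high_mult Multiplier defining the high threshold relative to the
#'   map-wide mean (default 5).
#' @return Tibble of class `overview_profile`: `chromosome`, `cm` (bin
#'   centers), `u`; attributes `nb_qtl`, `nb_experiments`,
#'   `mean_threshold` (map-wide mean of `u`), `high_threshold`
#'   (`high_mult` times the mean), `bin_cm`.
#' @export
overview_index <- function(mtas, ld, map_lengths, nb_experiments = NULL,
                           bin_cm = 1, high_mult = 5) {
  mtas <- tibble::as_tibble(mtas)
  ld <- normalize_ld(ld)
  ml <- tibble::as_tibble(map_lengths)
  if (!"length_cm" %in% names(ml) && "chrom_info" %in% class(ml)) {
    stop("map_lengths needs columns chromosome, length_cm")
  }
  stopifnot(all(c("chromosome", "length_cm") %in% names(ml)))
  if (any(ml$length_cm <= 0)) stop("zero map length")
  off_map <- setdiff(unique(mtas$chromosome), ml$chromosome)
  if (length(off_map)) {
    stop("MTA on unmapped chromosome(s): ", paste(off_map, collapse = ", "))
  }
  if (is.null(nb_experiments)) {
    stopifnot(all(c("trait", "environment") %in% names(mtas)))
    nb_experiments <- nrow(dplyr::distinct(mtas, .data$trait,
                                           .data$environment))
  }
  if (nb_experiments < 1) stop("`nb_experiments` must be >= 1")
  prof <- purrr::map_dfr(seq_len(nrow(ml)), function(i) {
    chrom <- ml$chromosome[i]
    L <- ml$length_cm[i]
    centers <- seq(bin_cm / 2, by = bin_cm, length.out = ceiling(L / bin_cm))
    u <- numeric(length(centers))
    q <- mtas[mtas$chromosome == chrom, ]
    if (nrow(q)) {
      s <- ld$s_cm[match(chrom, ld$chromosome)]
      if (is.na(s)) stop("no LD-decay entry for chromosome ", chrom)
      for (mu in q$cm) {
        u <- u + stats::pnorm((centers + bin_cm / 2 - mu) / s) -
          stats::pnorm((centers - bin_cm / 2 - mu) / s)
      }
      u <- u / nb_experiments
    }
    tibble::tibble(chromosome = chrom, cm = centers, u = u)
  })
  structure(prof,
            class = c("overview_profile", class(prof)),
            nb_qtl = nrow(mtas), nb_experiments = nb_experiments,
            mean_threshold = mean(prof$u),
            high_threshold = high_mult * mean(prof$u),
            bin_cm = bin_cm, high_mult = high_mult)
}

#' Call peaks of the overview index
#'
#' A peak is a strict local maximum of the index above a threshold
#' expressed as a multiple of the map-wide mean. Plateaus (runs of equal
#' values higher than both flanking bins) are resolved to their midpoint
#' bin. Every peak above `mean_mult * mean` is returned with a tier label:
#' `"high"` when it also clears `high_mult * mean`, otherwise `"mean"` —
#' so the high tier is always a subset of the mean tier.
#'
#' @param profile An `overview_profile`.
#' @param mean_mult Multiplier of the map-wide mean for the base
#'   threshold (default 1).
#' @param high_mult Multiplier for the high tier (default 5).
#' @return Tibble `chromosome`, `cm`, `u`, `tier`.
#' @export
call_peaks <- function(profile, mean_mult = 1, high_mult = 5) {
  if (!nrow(profile)) stop("empty overview profile")
  base_mean <- attr(profile, "mean_threshold")
  if (is.null(base_mean)) base_mean <- mean(profile$u)
  thr_mean <- mean_mult * base_mean
  thr_high <- high_mult * base_mean
  res <- purrr::map_dfr(split(tibble::as_tibble(profile),
                              profile$chromosome), function(d) {
    d <- dplyr::arrange(d, .data$cm)
    r <- rle(d$u)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nruns <- length(r$values)
    keep <- vapply(seq_len(nruns), function(k) {
      v <- r$values[k]
      left_ok <- k > 1 && r$values[k - 1] < v
      right_ok <- k < nruns && r$values[k + 1] < v
      # interior runs need both sides lower; edge runs the available side
      if (k == 1 && k == nruns) return(FALSE)        # flat profile
      if (k == 1) return(right_ok)
      if (k == nruns) return(left_ok)
      left_ok && right_ok
    }, logical(1))
    idx <- floor((starts[keep] + ends[keep]) / 2)
    tibble::tibble(chromosome = d$chromosome[idx], cm = d$cm[idx],
                   u = d$u[idx])
  })
  res <- dplyr::filter(res, .data$u > thr_mean)
  res$tier <- ifelse(res$u > thr_high, "high", "mean")
  dplyr::arrange(res, .data$chromosome, .data$cm)
}

#' Physical interval length in Mb
#'
#' `|right_bp - left_bp| / 1e6`, rounded half-up to one decimal. The
#' absolute value covers flanking markers whose physical order is reversed
#' relative to the genetic map.
#'
#' @param left_bp,right_bp Physical positions of the flanking markers.
#' @return Interval length in Mb, one decimal.
#' @export
#' @examples
#' physical_interval(7294564, 9579957)      # 2.3
#' physical_interval(613696030, 609166802)  # 4.5 (reversed order)
physical_interval <- function(left_bp, right_bp) {
  round_half_up(abs(right_bp - left_bp) / 1e6, 1)
}

# nearest mapped marker at/outside a cM bound on one chromosome
flank_marker <- function(map_chr, bound, side) {
  if (side == "left") {
    cand <- map_chr[map_chr$cm <= bound, ]
    if (!nrow(cand)) cand <- map_chr[which.min(map_chr$cm), ]
    cand[which.max(cand$cm), ]
  } else {
    cand <- map_chr[map_chr$cm >= bound, ]
    if (!nrow(cand)) cand <- map_chr[which.max(map_chr$cm), ]
    cand[which.min(cand$cm), ]
  }
}

#' Merge overview-index peaks into QTL hotspots
#'
#' Peaks on the same chromosome whose LD confidence windows
#' (`peak +- ci_cm / 2`) overlap are merged into one hotspot spanning
#' `[min lower, max upper]`. Member MTAs are all associations falling
#' inside the hotspot's genetic bounds; its trait and environment sets are
#' the unions over members, the reported peak is the merged peak with the
#' highest index value, flanking markers are the nearest mapped markers at
#' or outside the bounds, and the physical interval is their
#' [physical_interval()]. Hotspots are named `QTL<chromosome>.<ordinal>`
#' along each chromosome. A peak window containing no MTA is a
#' contradiction (peaks are built from MTA mass) and raises an error.
#'
#' @param peaks Peak table from [call_peaks()] (filter to the tier you want
#'   merged, typically `"high"`).
#' @param mtas The MTA table that produced the overview profile.
#' @param ld LD profile ([ld_profile()]).
#' @param map Marker map (`marker_id`, `chromosome`, `cm`, `bp`).
#' @param map_lengths Optional `chromosome`/`length_cm` table for clipping.
#' @param window_mult Multiplier on the CI window used for merging
#'   (default 1).
#' @return Tibble of class `hotspot_table`: `id`, `chromosome`, `left_cm`,
#'   `peak_cm`, `right_cm`, `n_mtas`, `max_neglog10p`, `n_environments`,
#'   `n_traits`, `traits`, `environments`, `left_marker`, `left_bp`,
#'   `right_marker`, `right_bp`, `ci_mb`, `member_mtas` (list-column).
#' @export
merge_to_hotspots <- function(peaks, mtas, ld, map, map_lengths = NULL,
                              window_mult = 1) {
  peaks <- tibble::as_tibble(peaks)
  if (!nrow(peaks)) {
    stop("no peaks to merge", call. = FALSE)
  }
  mtas <- tibble::as_tibble(mtas)
  ld <- normalize_ld(ld)
  map <- tibble::as_tibble(map)
  out <- purrr::map_dfr(split(peaks, peaks$chromosome), function(pk) {
    chrom <- pk$chromosome[1]
    ci <- ld$ci_cm[match(chrom, ld$chromosome)]
    if (is.na(ci)) stop("no LD-decay entry for chromosome ", chrom)
    L <- if (!is.null(map_lengths)) {
      ml <- tibble::as_tibble(map_lengths)
      ml$length_cm[match(chrom, ml$chromosome)]
    } else Inf
    pk <- dplyr::arrange(pk, .data$cm)
    lower <- pmax(pk$cm - window_mult * ci / 2, 0)
    upper <- pmin(pk$cm + window_mult * ci / 2, L)
    grp <- cumsum(c(1, as.integer(lower[-1] > cummax(upper[-length(upper)]))))
    map_chr <- map[map$chromosome == chrom, ]
    purrr::map_dfr(split(seq_len(nrow(pk)), grp), function(ii) {
      l <- min(lower[ii]); r <- max(upper[ii])
      peak_cm <- pk$cm[ii][which.max(pk$u[ii])]
      members <- mtas[mtas$chromosome == chrom & mtas$cm >= l &
                        mtas$cm <= r, ]
      if (!nrow(members)) {
        stop(sprintf(
          "hotspot window %s:[%.1f, %.1f] contains no MTA", chrom, l, r))
      }
      lm_ <- flank_marker(map_chr, l, "left")
      rm_ <- flank_marker(map_chr, r, "right")
      envs <- if ("environment" %in% names(members)) {
        sort(unique(members$environment))
      } else character()
      trs <- if ("trait" %in% names(members)) {
        sort(unique(members$trait))
      } else character()
      tibble::tibble(
        chromosome = chrom, left_cm = l, peak_cm = peak_cm, right_cm = r,
        n_mtas = nrow(members),
        max_neglog10p = if ("neglog10p" %in% names(members)) {
          max(members$neglog10p)
        } else NA_real_,
        n_environments = length(setdiff(envs, "mean")),
        n_traits = length(trs),
        traits = paste(trs, collapse = ","),
        environments = paste(envs, collapse = ","),
        left_marker = lm_$marker_id, left_bp = lm_$bp,
        right_marker = rm_$marker_id, right_bp = rm_$bp,
        ci_mb = physical_interval(lm_$bp, rm_$bp),
        member_mtas = list(members))
    })
  })
  out <- dplyr::arrange(out, .data$chromosome, .data$left_cm)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$chromosome),
    id = sprintf("QTL%s.%d", .data$chromosome, dplyr::row_number()))
  out <- dplyr::relocate(dplyr::ungroup(out), "id")
  structure(out, class = c("hotspot_table", class(out)))
}

#' Apply the hotspot exclusion rules
#'
#' Drops hotspots that (1) contain the chromosome's centromere within their
#' genetic bounds or have a physical confidence interval longer than
#' `max_ci_mb`, or (2) are supported by MTAs from fewer than `min_years`
#' environments or fewer than `min_traits` traits. Exclusion reasons are
#' logged per dropped hotspot in the `excluded` attribute.
#'
#' @param hotspots A `hotspot_table`.
#' @param centromeres Tibble `chromosome`, `centromere_cm`.
#' @param max_ci_mb Maximum physical CI length in Mb (default 35).
#' @param min_years Minimum number of distinct (year) environments
#'   (default 2).
#' @param min_traits Minimum number of distinct traits (default 2).
#' @return The retained hotspots; attribute `excluded` is a tibble
#'   (`id`, `reason`) naming every dropped hotspot.
#' @export
filter_hotspots <- function(hotspots, centromeres, max_ci_mb = 35,
                            min_years = 2, min_traits = 2) {
  hs <- tibble::as_tibble(hotspots)
  cen <- tibble::as_tibble(centromeres)
  stopifnot(all(c("chromosome", "centromere_cm") %in% names(cen)))
  missing_cen <- setdiff(unique(hs$chromosome), cen$chromosome)
  if (length(missing_cen)) {
    stop("missing centromere position for chromosome(s): ",
         paste(missing_cen, collapse = ", "))
  }
  hs <- dplyr::left_join(hs, cen[, c("chromosome", "centromere_cm")],
                         by = "chromosome")
  reasons <- purrr::map_chr(seq_len(nrow(hs)), function(i) {
    r <- character()
    if (hs$centromere_cm[i] >= hs$left_cm[i] &&
        hs$centromere_cm[i] <= hs$right_cm[i]) r <- c(r, "centromere")
    if (hs$ci_mb[i] > max_ci_mb) r <- c(r, "ci_gt_max")
    if (hs$n_environments[i] < min_years) r <- c(r, "single_year")
    if (hs$n_traits[i] < min_traits) r <- c(r, "few_traits")
    paste(r, collapse = ";")
  })
  excluded <- tibble::tibble(id = hs$id, reason = reasons)[nzchar(reasons), ]
  keep <- hs[!nzchar(reasons), ]
  keep$centromere_cm <- NULL
  structure(keep, class = c("hotspot_table", class(keep)),
            excluded = excluded)
}

#' Write hotspot physical intervals as BED
#'
#' Converts the 1-based inclusive flanking-marker interval to 0-based
#' half-open BED records for downstream annotation tools.
#'
#' @param hotspots A `hotspot_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
hotspots_to_bed <- function(hotspots, path) {
  hs <- tibble::as_tibble(hotspots)
  bed <- tibble::tibble(
    chrom = hs$chromosome,
    start = pmin(hs$left_bp, hs$right_bp) - 1,
    end = pmax(hs$left_bp, hs$right_bp),
    name = hs$id)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
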