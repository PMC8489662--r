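#' REML variance components and BLUPs for a multi-year trait
#'
#' Fits the augmented-design mixed model with the check entries as a fixed
#' effect and accession, year, accession-by-year, and row and column within
#' year as random effects, by REML (via \pkg{lme4}):
#' `value ~ check_group + (1|accession) + (1|year) + (1|accession:year) +
#' (1|year:row) + (1|year:column)`.
#' Accession BLUPs are the predicted genetic values used as GWAS responses
#' in the pooled ("mean") environment.
#'
#' @param tab Phenotype table: tibble with `plot_id`, `accession_id`,
#'   `year`, `row`, `column`, `is_check`, `trait`, `value`.
#' @param trait Trait name to fit.
#' @param include_spatial Include the row/column-within-year terms
#'   (default `TRUE`; turned off automatically when the table lacks the
#'   layout columns).
#' @return An object of class `vc_fit`: variance components
#'   (`sigma2_G`, `sigma2_E`, `sigma2_GE`, `sigma2_row`, `sigma2_col`,
#'   `sigma2_res`), accession BLUPs, and the underlying `lmerMod` fit.
#'   Supports `tidy()`, `glance()` and [heritability()].
#' @export
fit_mixed_model <- function(tab, trait, include_spatial = TRUE) {
  d <- dplyr::filter(tibble::as_tibble(tab), .data$trait == !!trait)
  if (!nrow(d)) stop("no records for trait '", trait, "'")
  if (dplyr::n_distinct(d$year) < 2) stop("need at least 2 years")
  if (dplyr::n_distinct(d$accession_id) < 2) stop("need at least 2 accessions")
  if (!"is_check" %in% names(d)) d$is_check <- FALSE
  d <- dplyr::mutate(
    d,
    check_group = factor(ifelse(.data$is_check,
                                paste0("check_", .data$accession_id), "test")),
    accession_id = factor(.data$accession_id),
    year = factor(.data$year))
  d$check_group <- stats::relevel(d$check_group, ref = "test")
  spatial <- include_spatial && all(c("row", "column") %in% names(d))
  form <- value ~ check_group + (1 | accession_id) + (1 | year) +
    (1 | accession_id:year)
  if (spatial) {
    form <- stats::update(form, . ~ . + (1 | year:row) + (1 | year:column))
  }
  fit <- suppressMessages(lme4::lmer(form, data = d, REML = TRUE,
                                     control = lme4::lmerControl(
                                       check.conv.singular = "ignore")))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  blup <- lme4::ranef(fit)$accession_id
  blups <- tibble::tibble(accession_id = rownames(blup),
                          blup = blup[["(Intercept)"]])
  structure(list(
    trait = trait,
    sigma2_G = get_vc("accession_id"),
    sigma2_E = get_vc("year"),
    sigma2_GE = get_vc("accession_id:year"),
    sigma2_row = get_vc("year:row"),
    sigma2_col = get_vc("year:column"),
    sigma2_res = get_vc("Residual"),
    blups = blups,
    n_years = nlevels(d$year),
    nobs = nrow(d),
    fit = fit), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf(
    "<vc_fit> trait '%s': sigma2_G = %.4g, sigma2_E = %.4g, sigma2_GE = %.4g, H2 = %.3f\n",
    x$trait, x$sigma2_G, x$sigma2_E, x$sigma2_GE, heritability(x)))
  invisible(x)
}

#' @method tidy vc_fit
#' @export
tidy.vc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("accession", "year", "accession:year", "year:row", "year:column",
             "residual"),
    variance = c(x$sigma2_G, x$sigma2_E, x$sigma2_GE, x$sigma2_row,
                 x$sigma2_col, x$sigma2_res))
}

#' @method glance vc_fit
#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(trait = x$trait, h2 = heritability(x),
                 logLik = as.numeric(stats::logLik(x$fit)),
                 nobs = x$nobs, n_years = x$n_years)
}

#' Broad-sense heritability (Knapp)
#'
#' `H2 = sigma2_G / (sigma2_G + sigma2_E + sigma2_GE)`: the genotypic share
#' of the across-year phenotypic variance, with the three components used
#' exactly as estimated (no division of the interaction by the number of
#' years; see the methods vignette for the conventional alternative).
#'
#' @param x A `vc_fit`, or the genotypic variance `sigma2_G`.
#' @param sigma2_E,sigma2_GE Year and genotype-by-year variances when `x`
#'   is numeric.
#' @return H2 in `[0, 1]`.
#' @export
#' @examples
#' heritability(9, 1, 0)  # 0.9
heritability <- function(x, sigma2_E = NULL, sigma2_GE = NULL) {
  if (inherits(x, "vc_fit")) {
    g <- x$sigma2_G; e <- x$sigma2_E; ge <- x$sigma2_GE
  } else {
    g <- x; e <- sigma2_E; ge <- sigma2_GE
  }
  stopifnot(is.numeric(g), is.numeric(e), is.numeric(ge),
            g >= 0, e >= 0, ge >= 0)
  tot <- g + e + ge
  if (tot == 0) stop("all variance components are zero")
  g / tot
}

#' Year / subpopulation variance partition
#'
#' Two-way fixed-effects ANOVA of a trait on year, subpopulation and their
#' interaction, with sequential (Type I) sums of squares in that order.
#' Each term's share is expressed as a percentage of the three-term sum,
#' summarising how much of the structured variation is seasonal versus
#' attributable to the panel's genetic subpopulations.
#'
#' @param tab Phenotype table (as in [fit_mixed_model()]).
#' @param trait Trait name.
#' @param grouping Tibble mapping `accession_id` to `subpop` (admixed
#'   accessions may carry their own label).
#' @return Tibble `term` (`year`, `subpop`, `year:subpop`), `ss`, `pct`;
#'   percentages sum to 100.
#' @export
variance_partition <- function(tab, trait, grouping) {
  d <- dplyr::filter(tibble::as_tibble(tab), .data$trait == !!trait)
  grouping <- tibble::as_tibble(grouping)
  stopifnot(all(c("accession_id", "subpop") %in% names(grouping)))
  unassigned <- setdiff(unique(d$accession_id), grouping$accession_id)
  if (length(unassigned)) {
    stop("accessions without a subpopulation: ",
         paste(utils::head(unassigned, 3), collapse = ", "))
  }
  d <- dplyr::inner_join(d, grouping, by = "accession_id")
  span <- dplyr::summarise(dplyr::group_by(d, .data$subpop),
                           ny = dplyr::n_distinct(.data$year), .groups = "drop")
  if (any(span$ny < 2)) {
    stop("subpopulation(s) present in a single year: ",
         paste(span$subpop[span$ny < 2], collapse = ", "))
  }
  d$year <- factor(d$year)
  d$subpop <- factor(d$subpop)
  a <- stats::aov(value ~ year * subpop, data = d)
  ss <- summary(a)[[1]][["Sum Sq"]]
  terms <- trimws(rownames(summary(a)[[1]]))
  keep <- match(c("year", "subpop", "year:subpop"), terms)
  ss <- ss[keep]
  tibble::tibble(term = c("year", "subpop", "year:subpop"),
                 ss = ss, pct = 100 * ss / sum(ss))
}

#' Accession-level trait means per environment
#'
#' Collapses plot records to accession means within each year and adds the
#' across-year `"mean"` environment, the inputs for per-environment GWAS
#' scans.
#'
#' @param tab Phenotype table.
#' @param include_checks Keep the replicated check accessions (default
#'   `TRUE`; they carry genotypes like any panel member).
#' @return Tibble `accession_id`, `environment`, `trait`, `value`.
#' @export
accession_means <- function(tab, include_checks = TRUE) {
  d <- tibble::as_tibble(tab)
  if (!include_checks && "is_check" %in% names(d)) {
    d <- dplyr::filter(d, !.data$is_check)
  }
  per_year <- dplyr::summarise(
    dplyr::group_by(d, .data$accession_id, environment = .data$year,
                    .data$trait),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  overall <- dplyr::summarise(
    dplyr::group_by(per_year, .data$accession_id, .data$trait),
    value = mean(.data$value), .groups = "drop")
  overall$environment <- "mean"
  dplyr::bind_rows(per_year, overall[, names(per_year)])
}
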