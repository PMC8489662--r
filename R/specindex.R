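# Registry of the six vegetation indices computed from the four camera
# bands (green 550, red 660, red-edge 735, NIR 790 nm). The algebra is
# pinned here once so tests can check it against independent arithmetic.
vi_defs <- list(
  NDVI = list(
    bands = c("nir", "red"),
    fun = function(g, r, re, n) (n - r) / (n + r),
    guard = function(g, r, re, n) ifelse(n + r == 0, "div_zero", "ok")),
  RDVI = list(
    bands = c("nir", "red"),
    fun = function(g, r, re, n) (n - r) / sqrt(n + r),
    guard = function(g, r, re, n) ifelse(n + r <= 0, "div_zero", "ok")),
  MSAVI = list(
    bands = c("nir", "red"),
    fun = function(g, r, re, n) (2 * n + 1 - sqrt((2 * n + 1)^2 - 8 * (n - r))) / 2,
    guard = function(g, r, re, n) {
      ifelse((2 * n + 1)^2 - 8 * (n - r) < 0, "neg_radicand", "ok")
    }),
  MTVI2 = list(
    bands = c("nir", "red", "green"),
    fun = function(g, r, re, n) {
      1.5 * (1.2 * (n - g) - 2.5 * (r - g)) /
        sqrt((2 * n + 1)^2 - (6 * n - 5 * sqrt(r)) - 0.5)
    },
    guard = function(g, r, re, n) {
      rad <- (2 * n + 1)^2 - (6 * n - 5 * sqrt(r)) - 0.5
      ifelse(r < 0, "neg_radicand",
             ifelse(rad < 0, "neg_radicand", ifelse(rad == 0, "div_zero", "ok")))
    }),
  GNDVI = list(
    bands = c("nir", "green"),
    fun = function(g, r, re, n) (n - g) / (n + g),
    guard = function(g, r, re, n) ifelse(n + g == 0, "div_zero", "ok")),
  TCARI_OSAVI = list(
    bands = c("nir", "rededge", "red", "green"),
    fun = function(g, r, re, n) {
      tcari <- 3 * ((re - r) - 0.2 * (re - g) * (re / r))
      osavi <- (1 + 0.16) * (n - r) / (n + r + 0.16)
      tcari / osavi
    },
    guard = function(g, r, re, n) {
      ifelse(r == 0 | n + r + 0.16 == 0 | n == r, "div_zero", "ok")
    })
)

#' Registry of supported vegetation indices
#'
#' @return Tibble with the index name and the bands it uses.
#' @export
vi_registry <- function() {
  tibble::tibble(
    index = names(vi_defs),
    bands = purrr::map_chr(vi_defs, ~ paste(.x$bands, collapse = ", ")))
}

#' Compute spectral vegetation indices from plot reflectances
#'
#' Takes a tidy table of per-plot band reflectances and returns one row per
#' plot and index. Structural indices: NDVI `(NIR-R)/(NIR+R)`, RDVI
#' `(NIR-R)/sqrt(NIR+R)`, MSAVI `(2 NIR + 1 - sqrt((2 NIR + 1)^2 -
#' 8(NIR-R)))/2`, MTVI2 `1.5 (1.2(NIR-G) - 2.5(R-G)) / sqrt((2 NIR + 1)^2 -
#' (6 NIR - 5 sqrt(R)) - 0.5)`, GNDVI `(NIR-G)/(NIR+G)`; chlorophyll index
#' TCARI/OSAVI `3((RE-R) - 0.2 (RE-G)(RE/R)) / ((1+0.16)(NIR-R)/(NIR+R+0.16))`.
#' Degenerate inputs (zero denominators, negative radicands) produce a
#' flagged record with `NA` value rather than a silent `NaN`.
#'
#' @param spectra Data frame with columns `plot_id`, `green`, `red`,
#'   `rededge`, `nir` (reflectances in `[0, 1]`) and optionally `stage`.
#' @param indices Character vector of indices to compute (default all six).
#' @return Tibble `plot_id`, `stage`, `index`, `value`, `flag` (`"ok"` or
#'   the failure reason).
#' @export
#' @examples
#' compute_vi(tibble::tibble(plot_id = "p1", green = 0.15, red = 0.1,
#'                           rededge = 0.3, nir = 0.8))
compute_vi <- function(spectra, indices = names(vi_defs)) {
  spectra <- tibble::as_tibble(spectra)
  need <- c("plot_id", "green", "red", "rededge", "nir")
  miss <- setdiff(need, names(spectra))
  if (length(miss)) stop("spectra missing columns: ", paste(miss, collapse = ", "))
  bands <- spectra[, c("green", "red", "rededge", "nir")]
  if (!all(vapply(bands, is.numeric, TRUE)) || any(!is.finite(as.matrix(bands)))) {
    stop("band reflectances must be finite numerics")
  }
  bad <- setdiff(indices, names(vi_defs))
  if (length(bad)) stop("unknown index: ", paste(bad, collapse = ", "))
  if (!"stage" %in% names(spectra)) spectra$stage <- NA_character_
  purrr::map_dfr(indices, function(ix) {
    d <- vi_defs[[ix]]
    flag <- d$guard(spectra$green, spectra$red, spectra$rededge, spectra$nir)
    val <- suppressWarnings(
      d$fun(spectra$green, spectra$red, spectra$rededge, spectra$nir))
    val[flag != "ok" | !is.finite(val)] <- NA_real_
    flag[flag == "ok" & is.na(val)] <- "nonfinite"
    tibble::tibble(plot_id = spectra$plot_id, stage = spectra$stage,
                   index = ix, value = val, flag = flag)
  })
}

#' Calibrate leaf area index against MTVI2
#'
#' Ordinary-least-squares fit of ceptometer-measured LAI on MTVI2 over the
#' calibration plots, `LAI = a + b * MTVI2`, the single-stage linear
#' transfer used to estimate LAI for every plot in a collection from a
#' small set of ground-truthed plots.
#'
#' @param vi Tibble from [compute_vi()] containing `MTVI2` rows (or any
#'   tibble with `plot_id` and `value` for the MTVI2 index).
#' @param lai_measured Data frame with `plot_id` and `lai` (m2/m2) for the
#'   calibration plots.
#' @return An object of class `lai_model` with `intercept`, `slope`,
#'   `r_squared`, `sigma`, `n` and the underlying `lm` fit. Supports
#'   [predict()], `tidy()` and `glance()`.
#' @export
calibrate_lai <- function(vi, lai_measured) {
  mt <- dplyr::filter(tibble::as_tibble(vi), .data$index == "MTVI2")
  if (!nrow(mt)) stop("no MTVI2 records in `vi`")
  d <- dplyr::inner_join(mt, tibble::as_tibble(lai_measured), by = "plot_id")
  d <- dplyr::filter(d, is.finite(.data$value), is.finite(.data$lai))
  if (nrow(d) < 2 || dplyr::n_distinct(d$value) < 2) {
    stop("need at least 2 calibration plots with distinct MTVI2 values")
  }
  fit <- stats::lm(lai ~ value, data = d)
  sm <- summary(fit)
  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    r_squared = sm$r.squared,
    sigma = sm$sigma,
    n = nrow(d),
    fit = fit), class = "lai_model")
}

#' Predict LAI from MTVI2 records
#'
#' @param object A `lai_model`.
#' @param vi Tibble with MTVI2 records (as for [calibrate_lai()]).
#' @param ... Unused.
#' @return Tibble `plot_id`, `stage`, `index = "LAI"`, `value`, `flag`.
#' @export
predict.lai_model <- function(object, vi, ...) {
  mt <- dplyr::filter(tibble::as_tibble(vi), .data$index == "MTVI2")
  tibble::tibble(
    plot_id = mt$plot_id,
    stage = if ("stage" %in% names(mt)) mt$stage else NA_character_,
    index = "LAI",
    value = object$intercept + object$slope * mt$value,
    flag = ifelse(is.finite(mt$value), "ok", "nonfinite"))
}

#' @export
print.lai_model <- function(x, ...) {
  cat(sprintf("<lai_model> LAI = %.4f + %.4f * MTVI2 (R^2 = %.3f, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy lai_model
#' @export
tidy.lai_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = c("(Intercept)", "MTVI2"),
                 estimate = c(x$intercept, x$slope),
                 std.error = sm[, "Std. Error"],
                 statistic = sm[, "t value"],
                 p.value = sm[, "Pr(>|t|)"])
}

#' @method glance lai_model
#' @export
glance.lai_model <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sigma = x$sigma, nobs = x$n)
}
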