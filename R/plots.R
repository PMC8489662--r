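#' Manhattan plot of scan records
#'
#' @param mtas Scan or MTA tibble (`chromosome`, `cm` or `bp`,
#'   `neglog10p`).
#' @param thresholds Optional tibble from [gwas_thresholds()]; drawn as
#'   horizontal lines.
#' @param position `"cm"` or `"bp"` for the x axis.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(mtas, thresholds = NULL, position = c("cm", "bp")) {
  position <- match.arg(position)
  d <- tibble::as_tibble(mtas)
  offs <- dplyr::mutate(
    dplyr::summarise(dplyr::group_by(d, .data$chromosome),
                     span = max(.data[[position]]), .groups = "drop"),
    offset = cumsum(dplyr::lag(.data$span, default = 0)))
  d <- dplyr::left_join(d, offs, by = "chromosome")
  d$x <- d[[position]] + d$offset
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$neglog10p,
                                       colour = .data$chromosome)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::labs(x = sprintf("cumulative position (%s)", position),
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    p <- p +
      ggplot2::geom_hline(yintercept = thresholds$suggestive,
                          linetype = "dashed") +
      ggplot2::geom_hline(yintercept = thresholds$corrected,
                          linetype = "dotted")
  }
  p
}

#' Plot the QTL overview index
#'
#' Index values along each chromosome with the map-wide mean and high
#' thresholds as dashed lines, optionally overlaying called peaks.
#'
#' @param profile An `overview_profile`.
#' @param peaks Optional peak tibble from [call_peaks()].
#' @return A ggplot object.
#' @export
plot_overview <- function(profile, peaks = NULL) {
  d <- tibble::as_tibble(profile)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$cm, y = .data$u)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(profile, "mean_threshold"),
                        linetype = "dashed", colour = "goldenrod") +
    ggplot2::geom_hline(yintercept = attr(profile, "high_threshold"),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~chromosome, scales = "free_x") +
    ggplot2::labs(x = "genetic position (cM)", y = "overview index") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p + ggplot2::geom_point(data = peaks,
                                 ggplot2::aes(shape = .data$tier),
                                 colour = "black", size = 2)
  }
  p
}

#' @rdname plot_overview
#' @param object An `overview_profile`.
#' @param ... Passed to [plot_overview()].
#' @method autoplot overview_profile
#' @export
autoplot.overview_profile <- function(object, ...) {
  plot_overview(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
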