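#' VanRaden genomic relationship (kinship) matrix
#'
#' Centered-dosage cross-product scaled by `2 * sum(p(1-p))` over the
#' markers used: `K = W W' / (2 sum p_j (1 - p_j))` with
#' `W = X - 2p`. Missing dosages are mean-imputed per marker; monomorphic
#' markers are dropped. The result is symmetric, positive semi-definite,
#' with diagonal near `1 + f` for inbreeding level `f`, and invariant to
#' marker order.
#'
#' @param panel A `genotype_panel`, or a dosage matrix (accessions x
#'   markers, values 0/1/2/NA).
#' @return Accession x accession kinship matrix.
#' @export
kinship <- function(panel) {
  X <- if (inherits(panel, "genotype_panel")) panel$dosages else panel
  stopifnot(is.matrix(X))
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1 & !is.nan(p)
  if (!any(poly)) stop("all markers are monomorphic; kinship undefined")
  X <- impute_dosages(X[, poly, drop = FALSE], center = FALSE)
  p <- p[poly]
  W <- sweep(X, 2, 2 * p)
  tcrossprod(W) / (2 * sum(p * (1 - p)))
}

#' Principal components of the genotype matrix
#'
#' @param panel A `genotype_panel`.
#' @param n_pcs Number of components.
#' @return Accession x `n_pcs` score matrix (centered dosages, unscaled).
#' @export
panel_pcs <- function(panel, n_pcs = 6) {
  X <- impute_dosages(panel$dosages, center = TRUE)
  if (n_pcs >= nrow(X)) stop("`n_pcs` must be smaller than the panel size")
  pr <- stats::prcomp(X, center = FALSE, scale. = FALSE, rank. = n_pcs)
  scores <- pr$x
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

# EMMA-style null-model REML: y = X b + u + e, u ~ N(0, sg^2 K),
# e ~ N(0, se^2 I). Profiles the restricted likelihood over
# delta = se^2/sg^2 using one eigendecomposition of K.
null_reml <- function(y, X, K) {
  n <- length(y)
  p <- ncol(X)
  eg <- eigen(K, symmetric = TRUE)
  U <- eg$vectors
  lam <- pmax(eg$values, 0)
  Uy <- crossprod(U, y)
  UX <- crossprod(U, X)
  rll <- function(logd) {
    d <- exp(logd)
    w <- 1 / (lam + d)
    XtWX <- crossprod(UX, UX * w)
    XtWy <- crossprod(UX, Uy * w)
    b <- solve(XtWX, XtWy)
    r <- Uy - UX %*% b
    rss <- sum(w * r^2)
    -0.5 * ((n - p) * log(rss / (n - p)) + sum(log(lam + d)) +
              determinant(XtWX, logarithm = TRUE)$modulus)
  }
  grid <- seq(-8, 8, length.out = 33)
  vals <- vapply(grid, rll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(rll, c(lo, hi), maximum = TRUE)
  d <- exp(opt$maximum)
  w <- 1 / (lam + d)
  XtWX <- crossprod(UX, UX * w)
  b <- solve(XtWX, crossprod(UX, Uy * w))
  r <- Uy - UX %*% b
  sg2 <- sum(w * r^2) / (n - p)
  list(U = U, lambda = lam, delta = d, sigma2_g = sg2, sigma2_e = d * sg2,
       sqrt_w = sqrt(w))
}

#' Mixed-linear-model association scan (PCA + K, P3D)
#'
#' Tests every marker in `y = marker + PCs + cofactors + u + e` with
#' `cov(u)` proportional to the kinship matrix. Variance components are
#' estimated once by REML on the null model (no marker) and reused for
#' every marker test — the population-parameters-previously-determined
#' (P3D) shortcut, equivalent to an uncompressed mixed model at those
#' components. After whitening by the null covariance the marker effect is
#' the partitioned-regression slope, tested with a t statistic on
#' `n - p - 1` degrees of freedom; the phenotypic variance explained (PVE)
#' is the marker's partial r-squared given PCs and cofactors. Records are
#' emitted for every testable marker regardless of significance;
#' thresholding is a downstream decision.
#'
#' With `method = "naive"` the scan is single-marker ordinary least squares
#' with no structure correction, the comparator whose genomic inflation the
#' mixed model is designed to remove.
#'
#' @param panel A QC-passed `genotype_panel`.
#' @param phenotypes Accession-level table: `accession_id` plus one column
#'   per trait (response and cofactors).
#' @param trait Name of the response column.
#' @param environment Environment label stamped on the output records
#'   (a year, or `"mean"`).
#' @param cofactors Character vector of cofactor column names (e.g.
#'   anthesis date); excluded automatically when equal to `trait`.
#' @param n_pcs Number of genotype principal components as fixed
#'   covariates (default 6).
#' @param method `"mlm"` (PCA + K) or `"naive"` (plain OLS, no PCs, no K).
#' @return Tibble of class `mta_scan`: `marker_id`, `chromosome`, `cm`,
#'   `bp`, `trait`, `environment`, `neglog10p`, `pve`, `effect`.
#'   Attributes: `vc` (null variance components), `skipped` (markers not
#'   testable, with reasons), `n` (accessions used).
#' @export
mlm_scan <- function(panel, phenotypes, trait, environment = "mean",
                     cofactors = character(), n_pcs = 6,
                     method = c("mlm", "naive")) {
  method <- match.arg(method)
  phenotypes <- tibble::as_tibble(phenotypes)
  stopifnot("accession_id" %in% names(phenotypes),
            trait %in% names(phenotypes))
  cofactors <- setdiff(cofactors, trait)
  keep_cols <- c("accession_id", trait, cofactors)
  ph <- stats::na.omit(phenotypes[, keep_cols])
  acc <- intersect(rownames(panel$dosages), ph$accession_id)
  if (length(acc) < 10) stop("phenotype and panel share too few accessions")
  ph <- ph[match(acc, ph$accession_id), ]
  y <- ph[[trait]]
  X <- panel$dosages[acc, , drop = FALSE]

  X0 <- cbind(`(Intercept)` = rep(1, length(acc)))
  if (method == "mlm") {
    if (n_pcs > 0) {
      sub <- genotype_panel(X, panel$map, chrom_info = panel$chrom_info)
      X0 <- cbind(X0, panel_pcs(sub, n_pcs))
    }
  }
  if (length(cofactors)) {
    X0 <- cbind(X0, as.matrix(ph[, cofactors, drop = FALSE]))
  }
  if (qr(X0)$rank < ncol(X0)) {
    stop(sprintf("singular fixed-effect design for trait '%s' (%s)",
                 trait, environment))
  }

  Xi <- impute_dosages(X, center = TRUE)
  if (method == "mlm") {
    K <- kinship(X)
    nr <- null_reml(y, X0, K)
    ys <- nr$sqrt_w * crossprod(nr$U, y)
    X0s <- nr$sqrt_w * crossprod(nr$U, X0)
    Ms <- nr$sqrt_w * crossprod(nr$U, Xi)
    vc <- tibble::tibble(sigma2_g = nr$sigma2_g, sigma2_e = nr$sigma2_e,
                         delta = nr$delta)
  } else {
    ys <- y
    X0s <- X0
    Ms <- Xi
    vc <- tibble::tibble(sigma2_g = NA_real_, sigma2_e = NA_real_,
                         delta = NA_real_)
  }

  # partitioned regression: project response and markers off the null design
  qr0 <- qr(X0s)
  ry <- as.numeric(qr.resid(qr0, ys))
  RM <- qr.resid(qr0, Ms)
  n <- length(ys)
  p0 <- ncol(X0s)
  df <- n - p0 - 1
  rxx <- colSums(RM^2)
  testable <- rxx > 1e-10
  beta <- rep(NA_real_, ncol(Ms))
  beta[testable] <- colSums(RM[, testable, drop = FALSE] * ry) / rxx[testable]
  rss0 <- sum(ry^2)
  rss1 <- rss0 - beta^2 * rxx
  tstat <- beta / sqrt(rss1 / df / rxx)
  pval <- 2 * stats::pt(-abs(tstat), df)
  pval <- pmax(pval, .Machine$double.xmin)  # keep p in (0, 1]
  pve <- tstat^2 / (tstat^2 + df)

  map <- panel$map[match(colnames(Ms), panel$map$marker_id), ]
  out <- tibble::tibble(
    marker_id = map$marker_id, chromosome = map$chromosome,
    cm = map$cm, bp = map$bp,
    trait = trait, environment = environment,
    neglog10p = -log10(pval), pve = pve, effect = beta)
  skipped <- tibble::tibble(marker_id = out$marker_id[!testable],
                            reason = "zero_variance")
  out <- out[testable, ]
  structure(out, class = c("mta_scan", class(out)),
            vc = vc, skipped = skipped, n = n)
}

#' Genomic inflation factor
#'
#' `lambda = median(chi^2) / qchisq(0.5, 1)` from per-marker p-values; 1
#' under a calibrated null, above 1 under uncorrected population-structure
#' confounding.
#'
#' @param neglog10p Vector of `-log10` p-values.
#' @return Scalar lambda.
#' @export
genomic_lambda <- function(neglog10p) {
  chi <- stats::qchisq(10^(-neglog10p), df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, 1)
}

#' Significance thresholds for the association scan
#'
#' The suggestive threshold is taken as given (conventionally
#' `-log10 p = 3`). The multiple-testing-corrected threshold is
#' `-log10(alpha / M_eff)` on the effective number of independent markers
#' implied by the panel's LD decay (3,696 by default), the fixed-count
#' construction used with LD-pruned marker sets.
#'
#' @param suggestive Suggestive `-log10 p` threshold.
#' @param fdr_alpha Significance level.
#' @param effective_markers Effective number of independent markers.
#' @return Tibble with `suggestive` and `corrected` thresholds
#'   (`-log10 p` scale).
#' @export
#' @examples
#' gwas_thresholds(3, 0.05, 3696)  # corrected ~ 4.87
gwas_thresholds <- function(suggestive = 3, fdr_alpha = 0.05,
                            effective_markers = 3696) {
  stopifnot(suggestive > 0, fdr_alpha > 0, fdr_alpha < 1)
  if (effective_markers <= 0) stop("`effective_markers` must be positive")
  tibble::tibble(suggestive = suggestive,
                 corrected = -log10(fdr_alpha / effective_markers))
}

#' Data-dependent Benjamini-Hochberg cutoff
#'
#' The alternative reading of an "FDR threshold": the largest p-value
#' admitted by the step-up procedure at level `alpha` over the observed
#' scan, returned on the `-log10` scale (`NA` when nothing passes).
#'
#' @param neglog10p Observed `-log10` p-values.
#' @param alpha FDR level.
#' @return Scalar `-log10 p` cutoff or `NA`.
#' @export
bh_threshold <- function(neglog10p, alpha = 0.05) {
  p <- sort(10^(-neglog10p))
  m <- length(p)
  ok <- which(p <= alpha * seq_len(m) / m)
  if (!length(ok)) return(NA_real_)
  -log10(p[max(ok)])
}
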