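#' Fit blood/cortex proportions to measured reflectance spectra
#'
#' Per pixel, least-squares fit of the time-mean calibrated reflectance
#' spectrum `Rd(lambda)` to a linear combination of the modeled blood and
#' cortex reflectance spectra, minimizing
#' `sum_lambda (Rd - (a_blood * Rblood + a_cortex * Rcortex))^2`.
#' Model and measured spectra are scaled to unit mean before fitting so the
#' coefficients reflect spectral shape proportions rather than illumination
#' intensity. The default solver constrains both coefficients to be
#' nonnegative (exact 2-variable active-set NNLS); coefficients are then
#' expressed in `[0, 1]` either by clipping (default) or by sum
#' normalization.
#'
#' @param measured `B x H x W` array (or `B`-vector, or `B x n` matrix) of
#'   time-mean calibrated reflectance per pixel.
#' @param r_blood,r_cortex `reflectance_spectrum` objects (or numeric
#'   vectors) on the same band grid.
#' @param nonneg constrain coefficients to be >= 0 (default TRUE).
#' @param normalization `"clip"` (default) or `"sum"`.
#' @return object of class `spectral_proportions`: list with `a_blood`,
#'   `a_cortex` (`H x W`, in `[0, 1]`), `residual` (`H x W` root sum of
#'   squares of the fit residual, on raw coefficients before normalization).
#' @export
fit_spectral_proportions <- function(measured, r_blood, r_cortex,
                                     nonneg = TRUE,
                                     normalization = c("clip", "sum")) {
  normalization <- match.arg(normalization)
  mb <- if (inherits(r_blood, "reflectance_spectrum")) r_blood$reflectance else as.numeric(r_blood)
  mc <- if (inherits(r_cortex, "reflectance_spectrum")) r_cortex$reflectance else as.numeric(r_cortex)
  if (length(mb) != length(mc)) stop("model spectra must share the band grid")
  mb <- mb / mean(mb)
  mc <- mc / mean(mc)
  m <- cbind(mb, mc)
  if (qr(m)$rank < 2L) stop("collinear model spectra: fit is rank-deficient")
  if (is.null(dim(measured))) measured <- matrix(measured, ncol = 1L)
  d <- dim(measured)
  if (d[1] != length(mb)) stop("measured spectra must be on the model band grid")
  spatial <- if (length(d) == 3L) d[2:3] else c(d[2], 1L)
  y <- measured
  dim(y) <- c(d[1], prod(spatial))
  ymean <- colMeans(y)
  ok <- is.finite(ymean) & ymean > 0
  y <- sweep(y, 2, ifelse(ok, ymean, NA_real_), "/")

  # normal equations, 2 unknowns, solved analytically per pixel
  g11 <- sum(mb * mb); g12 <- sum(mb * mc); g22 <- sum(mc * mc)
  det <- g11 * g22 - g12^2
  b1 <- colSums(y * mb); b2 <- colSums(y * mc)
  a1 <- (g22 * b1 - g12 * b2) / det
  a2 <- (g11 * b2 - g12 * b1) / det
  if (nonneg) {
    # active-set: if a coefficient goes negative, refit with it pinned at 0
    neg <- which(a1 < 0 | a2 < 0)
    if (length(neg)) {
      c1 <- pmax(b1[neg] / g11, 0)                   # blood-only candidate
      c2 <- pmax(b2[neg] / g22, 0)                   # cortex-only candidate
      yy <- colSums(y[, neg, drop = FALSE]^2)
      r1 <- yy - 2 * c1 * b1[neg] + c1^2 * g11
      r2 <- yy - 2 * c2 * b2[neg] + c2^2 * g22
      use1 <- r1 <= r2
      a1[neg] <- ifelse(use1, c1, 0)
      a2[neg] <- ifelse(use1, 0, c2)
    }
  }
  fit <- m %*% rbind(a1, a2)
  residual <- sqrt(colSums((y - fit)^2))
  if (normalization == "clip") {
    a1 <- pmin(pmax(a1, 0), 1)
    a2 <- pmin(pmax(a2, 0), 1)
  } else {
    s <- a1 + a2
    pos <- is.finite(s) & s > 0
    a1[pos] <- a1[pos] / s[pos]
    a2[pos] <- a2[pos] / s[pos]
    a1 <- pmin(pmax(a1, 0), 1)
    a2 <- pmin(pmax(a2, 0), 1)
  }
  a1[!ok] <- NA_real_; a2[!ok] <- NA_real_; residual[!ok] <- NA_real_
  structure(list(a_blood = matrix(a1, spatial[1], spatial[2]),
                 a_cortex = matrix(a2, spatial[1], spatial[2]),
                 residual = matrix(residual, spatial[1], spatial[2]),
                 normalization = normalization, nonneg = nonneg),
            class = "spectral_proportions")
}

#' Threshold spectral proportions into blood / cortex masks
#'
#' Strict-inequality thresholding: `a_blood > t_blood` marks blood,
#' `a_cortex > t_cortex` marks cortex. A pixel passing both tests (possible
#' because the coefficients are not constrained to sum to one) is assigned to
#' the larger coefficient; an exact tie stays unclassified.
#'
#' @param props a [fit_spectral_proportions()] result.
#' @param t_blood,t_cortex thresholds in `(0, 1)`; defaults 0.8 and 0.75.
#' @return list with `H x W` logical `blood`, `cortex` masks (mutually
#'   exclusive) and the thresholds used.
#' @export
classify_spectral <- function(props, t_blood = 0.8, t_cortex = 0.75) {
  stopifnot(inherits(props, "spectral_proportions"))
  if (t_blood <= 0 || t_blood >= 1 || t_cortex <= 0 || t_cortex >= 1)
    stop("thresholds must be in (0, 1)")
  ab <- props$a_blood; ac <- props$a_cortex
  blood <- !is.na(ab) & ab > t_blood
  cortex <- !is.na(ac) & ac > t_cortex
  both <- blood & cortex
  if (any(both)) {
    blood[both] <- ab[both] > ac[both]
    cortex[both] <- ac[both] > ab[both]
  }
  list(blood = blood, cortex = cortex, t_blood = t_blood, t_cortex = t_cortex)
}

#' Patient-specific dynamic threshold from a bleeding seed region
#'
#' The stated percentile (default 75th) of the band-metric values within the
#' user-supplied bleeding seed region, under the linear-interpolation
#' quantile convention (R type 7). This is the semi-automatic step: the seed
#' region stands in for the manual segmentation of an area of pooled blood.
#'
#' @param metric a [band_metric()] map.
#' @param bleeding_region nonempty `H x W` logical mask.
#' @param percentile percentile in `[0, 100]`, default 75.
#' @param exclude optional mask of pixels to drop first.
#' @return scalar threshold.
#' @export
dynamic_threshold <- function(metric, bleeding_region, percentile = 75,
                              exclude = NULL) {
  keep <- bleeding_region
  if (!is.null(exclude)) keep <- keep & !exclude
  v <- metric[keep]
  v <- v[is.finite(v)]
  if (!length(v)) stop("bleeding seed region is empty after mask exclusion")
  unname(stats::quantile(v, percentile / 100, type = 7))
}

#' Dynamic / static classification of the activity metric
#'
#' A pixel is dynamic (hemodynamic activity present) where the band metric
#' strictly exceeds the threshold, static otherwise; excluded pixels are
#' neither.
#'
#' @param metric a [band_metric()] map.
#' @param threshold finite scalar, e.g. from [dynamic_threshold()] or a
#'   manual override.
#' @param exclude optional `H x W` logical mask (excluded pixels set `NA`).
#' @return `H x W` logical matrix (TRUE = dynamic, NA = excluded).
#' @export
classify_dynamic <- function(metric, threshold, exclude = NULL) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  dyn <- metric > threshold
  if (!is.null(exclude)) dyn[exclude] <- NA
  dyn
}

#' Label levels used by the segmentation
#' @return character vector of the five label classes.
#' @export
segmentation_levels <- function() {
  c("cortex", "vessel", "bleeding", "specular", "unclassified")
}

#' Fuse spectral and dynamic masks into tissue labels
#'
#' Logical-intersection rule: blood & dynamic -> vessel; blood & static ->
#' bleeding; cortex & dynamic -> cortex; every other combination (including
#' cortex & static) -> unclassified. Specular pixels override everything.
#'
#' @param spectral list with `blood`, `cortex` masks from
#'   [classify_spectral()].
#' @param dynamic logical matrix from [classify_dynamic()].
#' @param specular optional specular mask.
#' @param threshold_used scalar recorded on the result.
#' @return object of class `segmentation_result`: `labels` (`H x W`
#'   character matrix over [segmentation_levels()]), the input masks, and
#'   `threshold_used`.
#' @export
fuse_labels <- function(spectral, dynamic, specular = NULL,
                        threshold_used = NA_real_) {
  blood <- spectral$blood; cortex <- spectral$cortex
  d <- dim(blood)
  if (!identical(d, dim(dynamic)) ||
      (!is.null(specular) && !identical(d, dim(specular))))
    stop("mask shapes differ")
  lab <- matrix("unclassified", d[1], d[2])
  dyn <- !is.na(dynamic) & dynamic
  sta <- !is.na(dynamic) & !dynamic
  lab[blood & dyn] <- "vessel"
  lab[blood & sta] <- "bleeding"
  lab[cortex & dyn] <- "cortex"
  if (!is.null(specular)) lab[specular] <- "specular"
  structure(list(labels = lab, dynamic_mask = dynamic,
                 blood_mask = blood, cortex_mask = cortex,
                 specular_mask = specular, threshold_used = threshold_used),
            class = "segmentation_result")
}

#' Label counts of a segmentation
#' @param x a `segmentation_result`.
#' @return named integer vector over the five classes.
#' @export
label_counts <- function(x) {
  stopifnot(inherits(x, "segmentation_result"))
  table(factor(as.character(x$labels), levels = segmentation_levels()))
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>\n")
  print(label_counts(x))
  cat(sprintf("dynamic threshold used: %s\n", format(x$threshold_used)))
  invisible(x)
}

#' @export
print.spectral_proportions <- function(x, ...) {
  cat(sprintf(
    "<spectral_proportions> %dx%d px (%s, %s); a_blood in [%.3g, %.3g]\n",
    nrow(x$a_blood), ncol(x$a_blood),
    if (x$nonneg) "nonnegative" else "unconstrained", x$normalization,
    min(x$a_blood, na.rm = TRUE), max(x$a_blood, na.rm = TRUE)))
  invisible(x)
}
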