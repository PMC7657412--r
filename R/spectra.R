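#' One-sided amplitude spectrum of per-pixel time series
#'
#' Removes the per-pixel temporal mean, applies a discrete Fourier transform
#' over the full analyzed window (no tapering or zero-padding by default) and
#' returns the one-sided magnitude spectrum on the grid `0, fps/N, ...,
#' fps/2`. Normalization: a unit-amplitude sinusoid at a grid frequency has
#' amplitude 1 at its bin (interior bins are `2|X_k|/N`; the zero and Nyquist
#' bins are not doubled).
#'
#' @param delta_hbo `T x H x W` array (or length-`T` vector) of
#'   concentration-change series.
#' @param fps sampling rate, Hz.
#' @param window `"none"` (default) or `"hann"`; tapering is exposed as an
#'   option but off by default.
#' @return object of class `frequency_spectrum`: `freqs_hz` (length
#'   `floor(N/2)+1`), `amplitude` (`F x H x W`), `fps`, `n_frames`,
#'   `snv = FALSE`.
#' @export
amplitude_spectrum <- function(delta_hbo, fps, window = c("none", "hann")) {
  window <- match.arg(window)
  if (is.null(dim(delta_hbo))) delta_hbo <- array(delta_hbo, c(length(delta_hbo), 1L, 1L))
  d <- dim(delta_hbo)
  n <- d[1]
  if (n < 16L) stop("need at least 16 frames")
  if (!is.finite(fps) || fps <= 0) stop("fps must be > 0")
  x <- delta_hbo
  dim(x) <- c(n, d[2] * d[3])
  x <- sweep(x, 2, colMeans(x), "-")
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    x <- x * w / mean(w)
  }
  f_count <- floor(n / 2) + 1L
  xf <- stats::mvfft(x)[seq_len(f_count), , drop = FALSE]
  amp <- Mod(xf) / n
  scale <- rep(2, f_count)
  scale[1] <- 1
  if (n %% 2 == 0) scale[f_count] <- 1
  amp <- amp * scale
  dim(amp) <- c(f_count, d[2], d[3])
  structure(list(freqs_hz = (seq_len(f_count) - 1L) * fps / n,
                 amplitude = amp, fps = fps, n_frames = n, snv = FALSE),
            class = "frequency_spectrum")
}

#' Standard normal variate normalization of amplitude spectra
#'
#' Per pixel, centers and scales the amplitude values to mean 0 and standard
#' deviation 1 so that the relative distribution of frequency components is
#' independent of absolute power. Statistics are computed over the retained
#' range `f >= f_min` (default 0.03 Hz): the zero-frequency bin reflects the
#' baseline choice and the slowest bins reflect drifts outside the
#' discriminative band, so both are excluded from the normalization
#' statistics (all `f > 0` bins are still z-transformed with those
#' statistics, which preserves the location of spectral peaks; if fewer than
#' two bins reach `f_min` the whole `f > 0` range is used instead). Pixels
#' with zero spread cannot be normalized and are set to `NA` with a reported
#' count.
#'
#' @param spectrum a raw `frequency_spectrum` from [amplitude_spectrum()].
#' @param f_min lower edge (Hz) of the range the normalization statistics
#'   are computed over.
#' @return `frequency_spectrum` with `snv = TRUE` and attribute
#'   `snv_f_min`.
#' @export
snv_normalize <- function(spectrum, f_min = 0.03) {
  stopifnot(inherits(spectrum, "frequency_spectrum"))
  if (spectrum$snv) return(spectrum)
  amp <- spectrum$amplitude
  d <- dim(amp)
  sel <- which(spectrum$freqs_hz >= f_min)
  sel <- setdiff(sel, 1L)
  if (length(sel) < 2L) sel <- 2:d[1]
  a <- amp[sel, , , drop = FALSE]
  dim(a) <- c(length(sel), d[2] * d[3])
  n_s <- length(sel)
  mu <- colMeans(a)
  sd <- sqrt(pmax(colMeans(a^2) - mu^2, 0) * n_s / (n_s - 1))
  zero <- !is.finite(sd) | sd == 0
  if (any(zero))
    message(sprintf("snv_normalize: %d pixel(s) with zero spectral spread excluded",
                    sum(zero)))
  sd[zero] <- NA_real_
  z <- amp[-1, , , drop = FALSE]
  dim(z) <- c(d[1] - 1L, d[2] * d[3])
  z <- sweep(sweep(z, 2, mu, "-"), 2, sd, "/")
  out <- array(0, d)
  dim(z) <- c(d[1] - 1L, d[2], d[3])
  out[-1, , ] <- z
  spectrum$amplitude <- out
  spectrum$snv <- TRUE
  attr(spectrum, "snv_f_min") <- f_min
  spectrum
}

#' Band-averaged hemodynamic activity metric
#'
#' Mean of the SNV-normalized amplitude over all frequency bins in the closed
#' interval `[f_lo, f_hi]`, per pixel. With the defaults this is the
#' 0.03-0.3 Hz metric that separates perfused tissue (respiratory and
#' low-frequency hemodynamic components present) from pooled blood.
#'
#' @param spectrum an SNV `frequency_spectrum` (a raw one is normalized
#'   first).
#' @param f_lo,f_hi band edges in Hz, inside `(0, fps/2]`.
#' @return `H x W` matrix of class `band_metric` with attribute
#'   `band = c(f_lo, f_hi)`.
#' @export
band_metric <- function(spectrum, f_lo = 0.03, f_hi = 0.3) {
  stopifnot(inherits(spectrum, "frequency_spectrum"))
  if (!spectrum$snv) spectrum <- snv_normalize(spectrum)
  if (f_lo <= 0 || f_hi > spectrum$fps / 2 || f_hi < f_lo)
    stop("band must lie inside (0, fps/2]")
  sel <- which(spectrum$freqs_hz >= f_lo & spectrum$freqs_hz <= f_hi)
  sel <- setdiff(sel, 1L)
  if (!length(sel)) {
    n_min <- ceiling(spectrum$fps / f_hi)
    stop(sprintf(
      "no frequency bins in [%g, %g] Hz at resolution %g Hz; need >= %d frames",
      f_lo, f_hi, spectrum$fps / spectrum$n_frames, n_min))
  }
  m <- apply(spectrum$amplitude[sel, , , drop = FALSE], c(2, 3), mean)
  structure(m, class = c("band_metric", class(m)), band = c(f_lo, f_hi))
}

#' Peak frequency within a band
#'
#' Frequency of maximal amplitude among bins in the closed band; ties break
#' toward the lower frequency. For a spatial spectrum the per-pixel mean
#' spectrum is used unless `pixel` selects one pixel.
#'
#' @param spectrum a `frequency_spectrum` (raw or SNV).
#' @param f_lo,f_hi band edges (Hz) within the grid.
#' @param pixel optional `c(row, col)`; default averages the amplitude over
#'   all pixels before locating the peak.
#' @return peak frequency in Hz.
#' @export
peak_frequency <- function(spectrum, f_lo, f_hi, pixel = NULL) {
  stopifnot(inherits(spectrum, "frequency_spectrum"))
  sel <- which(spectrum$freqs_hz >= f_lo & spectrum$freqs_hz <= f_hi)
  if (!length(sel)) stop("no frequency bins inside the requested band")
  amp <- spectrum$amplitude
  prof <- if (is.null(pixel)) {
    apply(amp[sel, , , drop = FALSE], 1, mean, na.rm = TRUE)
  } else {
    amp[sel, pixel[1], pixel[2]]
  }
  spectrum$freqs_hz[sel[which.max(prof)]]
}

#' Compare the band metric across labeled regions
#'
#' Kruskal-Wallis rank test of the band-metric distributions of the pixel
#' populations in each region (typically ground-truth or manually segmented
#' bleeding / vessel / cortex areas), with per-region quartiles for
#' whisker-plot style summaries.
#'
#' @param metric a [band_metric()] map.
#' @param regions named list of `H x W` logical masks (>= 2 regions).
#' @param exclude optional `H x W` logical mask of pixels to drop (e.g.
#'   specular).
#' @return object of class `region_comparison`: list with `statistic`
#'   (Kruskal-Wallis H), `p.value`, `df`, and `summary`, a tibble with one
#'   row per region (n, min, q25, median, q75, max, mean).
#' @export
region_compare <- function(metric, regions, exclude = NULL) {
  stopifnot(is.list(regions), length(regions) >= 2L)
  if (is.null(names(regions)) || any(names(regions) == ""))
    stop("regions must be a named list")
  vals <- lapply(regions, function(m) {
    keep <- m
    if (!is.null(exclude)) keep <- keep & !exclude
    v <- metric[keep]
    v[is.finite(v)]
  })
  if (any(lengths(vals) == 0L))
    stop("region(s) fully masked or empty: ",
         paste(names(vals)[lengths(vals) == 0L], collapse = ", "))
  kw <- stats::kruskal.test(vals)
  qs <- t(vapply(vals, stats::quantile, numeric(5),
                 probs = c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE))
  dimnames(qs) <- NULL
  summary <- tibble::tibble(
    region = names(vals), n = lengths(vals),
    min = qs[, 1], q25 = qs[, 2], median = qs[, 3], q75 = qs[, 4],
    max = qs[, 5], mean = vapply(vals, mean, numeric(1)))
  structure(list(statistic = unname(kw$statistic), p.value = kw$p.value,
                 df = unname(kw$parameter), summary = summary, values = vals),
            class = "region_comparison")
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4g, df = %d, p-value = %.3g\n",
              x$statistic, x$df, x$p.value))
  print(x$summary)
  invisible(x)
}

#' @export
print.frequency_spectrum <- function(x, ...) {
  d <- dim(x$amplitude)
  cat(sprintf(
    "<frequency_spectrum%s> %d bins 0-%g Hz (res %g Hz) x %dx%d px\n",
    if (x$snv) ", SNV" else "", d[1], max(x$freqs_hz),
    x$fps / x$n_frames, d[2], d[3]))
  invisible(x)
}
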