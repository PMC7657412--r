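#' Acquisition bookkeeping helpers
#'
#' Small exact conversions used throughout the acquisition-time analysis:
#' frames to seconds (`n / fps`), seconds to frames, the Nyquist frequency
#' (`fps / 2`), and the period of a frequency (`1 / f`). At 20 fps, 8 minutes
#' is 9600 frames, 3200 frames last 160 s, 500 frames 25 s, and the 0.03 Hz
#' band edge has a 33.3 s period.
#'
#' @param n_frames frame count.
#' @param fps frame rate, Hz.
#' @param seconds duration, s.
#' @param freq_hz frequency, Hz.
#' @name acquisition
NULL

#' @rdname acquisition
#' @export
frames_to_seconds <- function(n_frames, fps) n_frames / fps

#' @rdname acquisition
#' @export
seconds_to_frames <- function(seconds, fps) seconds * fps

#' @rdname acquisition
#' @export
nyquist_hz <- function(fps) fps / 2

#' @rdname acquisition
#' @export
period_s <- function(freq_hz) 1 / freq_hz

#' Frequency-band feasibility for a window length
#'
#' Whether an `n_frames`-long window at `fps` yields at least one nonzero
#' frequency bin inside the closed band `[f_lo, f_hi]` (bin spacing
#' `fps / n_frames`), and whether the lower band edge is fully resolvable
#' (window at least one period of `f_lo`, i.e. `n_frames / fps >= 1 / f_lo`).
#'
#' @param n_frames window length in frames.
#' @param fps frame rate, Hz.
#' @param f_lo,f_hi band edges, Hz.
#' @return list with logicals `feasible` (>= 1 bin in band) and
#'   `lower_edge_resolved`, plus `n_bins` and `df` (bin spacing, Hz).
#' @export
band_feasibility <- function(n_frames, fps, f_lo = 0.03, f_hi = 0.3) {
  df <- fps / n_frames
  k <- seq_len(floor(n_frames / 2))
  n_bins <- sum(k * df >= f_lo & k * df <= f_hi)
  list(feasible = n_bins >= 1L,
       lower_edge_resolved = n_frames / fps >= 1 / f_lo,
       n_bins = n_bins, df = df)
}

#' Segmentation stability versus acquisition window length
#'
#' For each candidate window length `n`, splits the dHbO series into
#' consecutive windows of `n` frames starting at frame 1 (disjoint by
#' default, or sliding with a stride), computes the SNV band metric on each
#' window, and compares it with the metric of the reference window (the
#' first `reference_n` frames). The deviation statistic is the mean absolute
#' deviation over unmasked pixels, normalized by the mean absolute reference
#' metric, in percent; it is averaged over the windows of each `n`.
#' Optionally, a caller-supplied labeling function is applied to each
#' window's metric to report the fraction of pixels whose label matches the
#' reference labeling.
#'
#' @param delta_hbo `T x H x W` array of dHbO series (uM).
#' @param fps frame rate, Hz.
#' @param n_values candidate window lengths (frames); default
#'   `seq(100, 3600, by = 100)` restricted to the available length.
#' @param reference_n reference window length (frames), default 3200 (or the
#'   full length if shorter).
#' @param f_lo,f_hi metric band (Hz), default 0.03-0.3.
#' @param placement `"disjoint"` (default) or `"sliding"`.
#' @param stride stride in frames for sliding placement (default `n/2`).
#' @param label_fun optional `function(metric_matrix) -> label matrix`; when
#'   given, per-window label agreement against the reference labeling is
#'   reported.
#' @param exclude optional `H x W` logical mask of pixels to ignore.
#' @return tibble of class `sweep_result`: one row per `n` with
#'   `n_frames`, `duration_s`, `n_windows`, `n_bins`, `feasible`,
#'   `variation_pct`, `label_agreement`. Infeasible window lengths are kept
#'   with `NA` statistics, never silently dropped.
#' @export
window_sweep <- function(delta_hbo, fps,
                         n_values = seq(100, 3600, by = 100),
                         reference_n = 3200,
                         f_lo = 0.03, f_hi = 0.3,
                         placement = c("disjoint", "sliding"),
                         stride = NULL, label_fun = NULL, exclude = NULL) {
  placement <- match.arg(placement)
  d <- dim(delta_hbo)
  total <- d[1]
  reference_n <- min(reference_n, total)
  n_values <- n_values[n_values <= total]
  if (!length(n_values)) stop("no candidate window length fits the series")
  keep <- if (is.null(exclude)) matrix(TRUE, d[2], d[3]) else !exclude

  metric_of <- function(from, n) {
    x <- delta_hbo[from:(from + n - 1), , , drop = FALSE]
    band_metric(snv_normalize(amplitude_spectrum(x, fps)), f_lo, f_hi)
  }
  ref_metric <- metric_of(1L, reference_n)
  ref_scale <- mean(abs(ref_metric[keep]), na.rm = TRUE)
  ref_labels <- if (!is.null(label_fun)) label_fun(ref_metric) else NULL

  rows <- lapply(n_values, function(n) {
    fb <- band_feasibility(n, fps, f_lo, f_hi)
    if (!fb$feasible) {
      return(tibble::tibble(n_frames = n, duration_s = n / fps,
                            n_windows = 0L, n_bins = fb$n_bins,
                            feasible = FALSE, variation_pct = NA_real_,
                            label_agreement = NA_real_))
    }
    step <- if (placement == "disjoint") n else max(1L, stride %||% (n %/% 2L))
    starts <- seq(1L, total - n + 1L, by = step)
    devs <- numeric(length(starts))
    agr <- numeric(length(starts))
    for (i in seq_along(starts)) {
      m <- metric_of(starts[i], n)
      devs[i] <- 100 * mean(abs(m[keep] - ref_metric[keep]), na.rm = TRUE) / ref_scale
      if (!is.null(ref_labels)) {
        l <- label_fun(m)
        agr[i] <- mean(l[keep] == ref_labels[keep], na.rm = TRUE)
      }
    }
    tibble::tibble(n_frames = n, duration_s = n / fps,
                   n_windows = length(starts), n_bins = fb$n_bins,
                   feasible = TRUE, variation_pct = mean(devs),
                   label_agreement = if (is.null(ref_labels)) NA_real_ else mean(agr))
  })
  out <- do.call(rbind, rows)
  attr(out, "reference_n") <- reference_n
  attr(out, "band") <- c(f_lo, f_hi)
  class(out) <- c("sweep_result", class(out))
  out
}
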