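#' Fixed label palette
#'
#' Colors matching the method's conventional legend: cortex green, vessels
#' blue, bleeding red, specular gray, unclassified black.
#' @return named character vector of colors.
#' @export
label_palette <- function() {
  c(cortex = "#2e9e4f", vessel = "#2b6fd6", bleeding = "#d63b2b",
    specular = "#9b9b9b", unclassified = "#000000")
}

# long-format helper for H x W matrices
matrix_to_df <- function(m, value = "value") {
  df <- data.frame(row = rep(seq_len(nrow(m)), ncol(m)),
                   col = rep(seq_len(ncol(m)), each = nrow(m)),
                   v = as.vector(m))
  names(df)[3] <- value
  df
}

#' Plot a segmentation label map
#'
#' @param x a `segmentation_result` (or `hemoseg_run`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_labels <- function(x, ...) {
  if (inherits(x, "hemoseg_run")) x <- x$segmentation
  stopifnot(inherits(x, "segmentation_result"))
  df <- matrix_to_df(x$labels, "label")
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row,
                                   fill = label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = label_palette(), drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot the band-averaged activity metric map
#'
#' @param metric a [band_metric()] map.
#' @return a ggplot object.
#' @export
plot_metric <- function(metric) {
  df <- matrix_to_df(unclass(metric), "metric")
  band <- attr(metric, "band")
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row,
                                   fill = metric)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = sprintf("SNV %.3g-%.3g Hz", band[1], band[2])) +
    ggplot2::theme_minimal()
}

#' Plot region-mean SNV amplitude spectra
#'
#' Mean SNV-normalized amplitude spectrum of each region, on a log-frequency
#' axis: the usual display where the 1/f trend, respiratory fundamental and
#' harmonic, and cardiac peak are identified.
#'
#' @param spectrum an SNV `frequency_spectrum`.
#' @param regions named list of `H x W` logical masks.
#' @param f_max truncate the frequency axis (Hz); default `fps/2`.
#' @return a ggplot object.
#' @export
plot_region_spectra <- function(spectrum, regions, f_max = NULL) {
  stopifnot(inherits(spectrum, "frequency_spectrum"))
  f <- spectrum$freqs_hz
  sel <- which(f > 0 & f <= (f_max %||% (spectrum$fps / 2)))
  amp <- spectrum$amplitude
  dfs <- lapply(names(regions), function(nm) {
    idx <- which(regions[[nm]])
    a <- apply(array(amp[sel, , ], c(length(sel), dim(amp)[2] * dim(amp)[3]))[, idx, drop = FALSE],
               1, mean, na.rm = TRUE)
    data.frame(freq_hz = f[sel], amplitude = a, region = nm)
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = freq_hz, y = amplitude,
                                   color = region)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "temporal frequency (Hz)", y = "SNV amplitude") +
    ggplot2::theme_minimal()
}

#' Plot a window-sweep result
#'
#' Variation of the band metric (percent, against the reference window)
#' versus acquisition duration.
#'
#' @param x a `sweep_result` tibble from [window_sweep()].
#' @return a ggplot object.
#' @export
plot_sweep <- function(x) {
  stopifnot(inherits(x, "sweep_result"))
  df <- x[x$feasible, ]
  ggplot2::ggplot(df, ggplot2::aes(x = duration_s,
                                   y = variation_pct)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "acquisition duration (s)",
                  y = "band-metric variation vs reference (%)") +
    ggplot2::theme_minimal()
}
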