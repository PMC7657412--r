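# shared fixtures; the default phantom and its pipeline run are expensive, so
# they are built once per test session and cached
.cache <- new.env(parent = emptyenv())

default_phantom <- function() {
  if (is.null(.cache$phantom)) .cache$phantom <- generate_phantom(phantom_spec())
  .cache$phantom
}

default_run <- function() {
  if (is.null(.cache$run))
    .cache$run <- suppressMessages(run_pipeline(default_phantom()))
  .cache$run
}

small_ext <- function() hb_extinction()

# tiny calibrated cube with constant per-band reflectance, for IO/mask tests
tiny_cube <- function(t = 4, h = 6, w = 5, fps = 20, value = NULL) {
  bands <- default_band_centers()
  data <- array(0, c(t, length(bands), h, w))
  v <- value %||% (seq_along(bands) / (2 * length(bands)))
  for (b in seq_along(bands)) data[, b, , ] <- v[min(b, length(v))]
  spectral_cube(data, fps, bands, calibrated = TRUE, saturation_value = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 4-neighborhood erosion used for boundary-tolerant recall
erode1 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  sh <- function(dr, dc) {
    out <- matrix(FALSE, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- mask[rs - dr, cs - dc]
    out
  }
  mask & sh(1, 0) & sh(-1, 0) & sh(0, 1) & sh(0, -1)
}

# ensemble of independent pixel realizations of one amplitude set, T x k array
signal_ensemble <- function(params, n_frames, fps, k = 32, seed = 0, ...) {
  out <- array(0, c(n_frames, k, 1))
  for (i in seq_len(k)) {
    out[, i, 1] <- hemodynamic_signal(params, n_frames, fps,
                                      seed = seed * 1009 + i, ...)$delta_hbo
  }
  out
}
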