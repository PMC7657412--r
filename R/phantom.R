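#' Default per-class hemodynamic amplitude sets
#'
#' Amplitudes (uM) of the signal components per tissue class: `a_1f`
#' (1/f-shaped background), `a_resp` (respiratory fundamental), `a_resp2`
#' (its second harmonic), `a_card` (cardiac), and `a_white` (flat
#' instrument-noise floor). Only the ordering of the classes is constrained
#' by the physiology the phantom emulates — perfused cortex strongest,
#' vessels intermediate, pooled blood with essentially no hemodynamics and a
#' noise-dominated (flat) spectrum; the magnitudes are package defaults (see
#' the methods vignette).
#'
#' @return named list of per-class amplitude lists.
#' @export
default_class_amplitudes <- function() {
  list(
    cortex   = list(a_1f = 0.30, a_resp = 1.00, a_resp2 = 0.30,
                    a_card = 0.40, a_white = 0.01),
    vessel   = list(a_1f = 0.08, a_resp = 0.22, a_resp2 = 0.06,
                    a_card = 0.40, a_white = 0.06),
    bleeding = list(a_1f = 0.004, a_resp = 0.00, a_resp2 = 0.00,
                    a_card = 0.00, a_white = 0.10))
}

#' Synthetic per-class hemodynamic signal
#'
#' Zero-mean oxyhemoglobin concentration-change series built as the sum of:
#' seeded 1/f Gaussian noise (one-sided amplitude spectrum `a_1f * (0.1
#' Hz/f)`, synthesized by frequency-domain shaping of white Gaussian noise),
#' a respiratory waveform at `respiration_hz` (sinusoid by default, or a
#' half-rectified sinusoid whose harmonics emulate a non-sinusoidal breath),
#' a sinusoid at twice the respiratory rate, a cardiac sinusoid, and an
#' optional white Gaussian floor. The deoxyhemoglobin series is generated as
#' `-rho * dHbO` plus independent small noise.
#'
#' @param params amplitude list with `a_1f`, `a_resp`, `a_resp2`, `a_card`
#'   and optional `a_white` (uM), e.g. one element of
#'   [default_class_amplitudes()].
#' @param n_frames number of frames (>= 64).
#' @param fps sampling rate, Hz.
#' @param seed RNG seed for the stochastic components.
#' @param respiration_hz,cardiac_hz component frequencies (Hz), below
#'   `fps/2`.
#' @param resp_waveform `"sine"` or `"half_rectified"`.
#' @param rho anticorrelation coefficient of dHbR against dHbO (default 0.3).
#' @param hbr_sigma sd (uM) of the independent noise on dHbR.
#' @return list with numeric vectors `delta_hbo`, `delta_hbr` (uM, zero
#'   mean).
#' @export
hemodynamic_signal <- function(params, n_frames, fps, seed = 0,
                               respiration_hz = 14 / 60,
                               cardiac_hz = 79 / 60,
                               resp_waveform = c("sine", "half_rectified"),
                               rho = 0.3, hbr_sigma = 0.02) {
  resp_waveform <- match.arg(resp_waveform)
  if (n_frames < 64L) stop("n_frames must be >= 64")
  if (respiration_hz >= fps / 2 || cardiac_hz >= fps / 2)
    stop("component frequencies must be below the Nyquist frequency fps/2")
  set.seed(seed)
  t <- (seq_len(n_frames) - 1) / fps
  a <- function(x) if (is.null(x)) 0 else x
  x <- numeric(n_frames)
  if (a(params$a_1f) > 0)
    x <- x + one_over_f_noise(n_frames, fps, params$a_1f)
  if (a(params$a_resp) > 0) {
    resp <- sin(2 * pi * respiration_hz * t)
    if (resp_waveform == "half_rectified") resp <- pmax(resp, 0)
    x <- x + params$a_resp * resp
  }
  if (a(params$a_resp2) > 0)
    x <- x + params$a_resp2 * sin(2 * pi * 2 * respiration_hz * t + pi / 5)
  if (a(params$a_card) > 0)
    x <- x + params$a_card * sin(2 * pi * cardiac_hz * t + pi / 3)
  if (a(params$a_white) > 0)
    x <- x + stats::rnorm(n_frames, sd = params$a_white)
  x <- x - mean(x)
  hbr <- -rho * x
  if (hbr_sigma > 0) hbr <- hbr + stats::rnorm(n_frames, sd = hbr_sigma)
  hbr <- hbr - mean(hbr)
  list(delta_hbo = x, delta_hbr = hbr)
}

# 1/f (amplitude ~ 1/f) Gaussian noise via frequency-domain shaping; `amp` is
# the expected one-sided amplitude at the 0.1 Hz reference frequency.
one_over_f_noise <- function(n, fps, amp, f_ref = 0.1) {
  nf <- floor(n / 2)
  f <- (1:nf) * fps / n
  mag <- amp * (f_ref / f) * n / 2          # complex-spectrum magnitude
  z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) / sqrt(2)
  spec <- complex(real = numeric(n))
  spec[2:(nf + 1)] <- mag * z
  if (n %% 2 == 0) spec[nf + 1] <- complex(real = mag[nf] * stats::rnorm(1))
  k_conj <- 2:(if (n %% 2 == 0) nf else nf + 1)
  spec[n + 2 - k_conj] <- Conj(spec[k_conj])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x - mean(x)
}

#' Phantom specification
#'
#' Parameters of the synthetic multispectral video phantom: scene geometry,
#' acquisition settings mirroring the snapshot-mosaic system (20 fps, 16
#' bands 480-630 nm), physiological rates (respiration 14 cycles/min,
#' cardiac 79 beats/min), per-class amplitude sets, optical presets, band
#' noise, specular spots, and the RNG seed.
#'
#' @param height,width spatial size in pixels.
#' @param n_frames frame count.
#' @param fps frame rate (Hz).
#' @param band_centers_nm 16 band centers (nm).
#' @param respiration_hz,cardiac_hz physiological rates (Hz), below `fps/2`.
#' @param amplitudes per-class amplitude sets; see
#'   [default_class_amplitudes()].
#' @param resp_waveform respiratory waveform shape for all classes.
#' @param rho,hbr_sigma dHbR coupling; see [hemodynamic_signal()].
#' @param noise_sigma relative (multiplicative) Gaussian band noise sd;
#'   default 0 (noise-free cube; per-class signal noise still applies).
#' @param specular_spots list of discs `list(row, col, radius)`; `NULL`
#'   disables them.
#' @param blood_model,cortex_model tissue presets (names or
#'   [tissue_model()]s) for the baseline reflectance and the DPF.
#' @param saturation_value detector maximum in reflectance units.
#' @param seed RNG seed; the phantom is bit-reproducible given the seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 64, width = 64, n_frames = 1200, fps = 20,
                         band_centers_nm = default_band_centers(),
                         respiration_hz = 14 / 60, cardiac_hz = 79 / 60,
                         amplitudes = default_class_amplitudes(),
                         resp_waveform = "sine",
                         rho = 0.3, hbr_sigma = 0.02,
                         noise_sigma = 0,
                         specular_spots = list(
                           list(row = 10, col = 52, radius = 2),
                           list(row = 50, col = 12, radius = 3)),
                         blood_model = "blood_patient1",
                         cortex_model = "cortex_patient1",
                         saturation_value = 1.0, seed = 0) {
  if (respiration_hz >= fps / 2 || cardiac_hz >= fps / 2)
    stop("physiological rates must be below fps/2")
  stopifnot(height >= 16, width >= 16, n_frames >= 64, fps > 0)
  structure(list(height = height, width = width, n_frames = n_frames,
                 fps = fps, band_centers_nm = band_centers_nm,
                 respiration_hz = respiration_hz, cardiac_hz = cardiac_hz,
                 amplitudes = amplitudes, resp_waveform = resp_waveform,
                 rho = rho, hbr_sigma = hbr_sigma, noise_sigma = noise_sigma,
                 specular_spots = specular_spots,
                 blood_model = blood_model, cortex_model = cortex_model,
                 saturation_value = saturation_value, seed = seed),
            class = "phantom_spec")
}

# deterministic scene: cortex background, two vessel curves, one bleeding
# ellipse; returns an H x W character label matrix (without specular spots)
phantom_scene <- function(height, width) {
  lab <- matrix("cortex", height, width)
  rows <- matrix(rep(seq_len(height), width), height, width)
  cols <- matrix(rep(seq_len(width), each = height), height, width)
  # vessel 1: gentle sinusoidal curve across the image, ~3 px wide
  c1 <- 0.30 * height + 0.12 * height * sin(2 * pi * (seq_len(width)) / width)
  v1 <- abs(rows - matrix(rep(c1, each = height), height, width)) <= 1.5
  # vessel 2: oblique line in the lower half, ~2 px wide
  c2 <- 0.85 * height - 0.45 * seq_len(width)
  v2 <- abs(rows - matrix(rep(c2, each = height), height, width)) <= 1.0 &
    cols <= 0.75 * width
  lab[v1 | v2] <- "vessel"
  # bleeding: elliptical blob
  er <- 0.62 * height; ec <- 0.70 * width
  ell <- ((rows - er) / (0.14 * height))^2 + ((cols - ec) / (0.19 * width))^2 <= 1
  lab[ell] <- "bleeding"
  lab
}

#' Generate a synthetic multispectral video phantom
#'
#' Builds a calibrated reflectance cube with ground truth. Per class, a
#' baseline reflectance spectrum comes from the class's tissue optical model
#' through the diffusion-approximation forward model (blood optics for both
#' vessels and bleeding, cortex optics for the background); every pixel of a
#' class shares that class's seeded hemodynamic time series, applied through
#' the forward modified Beer-Lambert law with the same extinction table and
#' DPF the inversion uses. Optional multiplicative Gaussian band noise;
#' specular discs are set to the saturation value. Bit-reproducible from the
#' seed.
#'
#' @param spec a [phantom_spec()].
#' @param ext an [extinction_table()]; default [hb_extinction()].
#' @return list of class `phantom`: `cube` (a calibrated [spectral_cube()]),
#'   `truth` (list with `labels` `H x W` character matrix including
#'   `specular`, per-class masks, `delta_hbo_true`/`delta_hbr_true`
#'   (`T x H x W`), and the class series), `dpf`, `spec`.
#' @export
generate_phantom <- function(spec, ext = hb_extinction()) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width; n <- spec$n_frames
  bands <- spec$band_centers_nm
  nb <- length(bands)
  as_model <- function(m) if (inherits(m, "tissue_model")) m else tissue_preset(m)
  blood <- as_model(spec$blood_model)
  cortex <- as_model(spec$cortex_model)
  dpf <- dpf_for_model(cortex, ext, bands)

  lab <- phantom_scene(h, w)
  classes <- c("cortex", "vessel", "bleeding")
  base_model <- list(cortex = cortex, vessel = blood, bleeding = blood)
  signals <- list()
  cube <- array(NA_real_, c(n, nb, h * w))
  hbo_true <- array(0, c(n, h * w))
  hbr_true <- array(0, c(n, h * w))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    sig <- hemodynamic_signal(spec$amplitudes[[cl]], n, spec$fps,
                              seed = spec$seed * 97 + ci,
                              respiration_hz = spec$respiration_hz,
                              cardiac_hz = spec$cardiac_hz,
                              resp_waveform = spec$resp_waveform,
                              rho = spec$rho, hbr_sigma = spec$hbr_sigma)
    signals[[cl]] <- sig
    r0 <- model_reflectance_spectrum(base_model[[cl]], ext, bands)$reflectance
    da <- forward_mbll(sig$delta_hbo, sig$delta_hbr, ext, dpf, bands)  # T x B
    block <- 10^(-da) * rep(r0, each = n)                              # T x B
    idx <- which(lab == cl)
    cube[, , idx] <- rep(as.vector(block), length(idx))
    hbo_true[, idx] <- rep(sig$delta_hbo, length(idx))
    hbr_true[, idx] <- rep(sig$delta_hbr, length(idx))
  }
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed * 97 + 11)
    cube <- cube * (1 + stats::rnorm(length(cube), sd = spec$noise_sigma))
    cube[cube <= 0] <- .Machine$double.eps
  }
  spec_mask <- matrix(FALSE, h, w)
  for (s in spec$specular_spots %||% list()) {
    rows <- matrix(rep(seq_len(h), w), h, w)
    cols <- matrix(rep(seq_len(w), each = h), h, w)
    disc <- (rows - s$row)^2 + (cols - s$col)^2 <= s$radius^2
    spec_mask <- spec_mask | disc
  }
  if (any(spec_mask)) cube[, , which(spec_mask)] <- spec$saturation_value
  dim(cube) <- c(n, nb, h, w)
  dim(hbo_true) <- c(n, h, w)
  dim(hbr_true) <- c(n, h, w)
  lab_full <- lab
  lab_full[spec_mask] <- "specular"
  out_cube <- spectral_cube(cube, spec$fps, bands, calibrated = TRUE,
                            saturation_value = spec$saturation_value)
  truth <- list(labels = lab_full,
                masks = list(cortex = lab_full == "cortex",
                             vessel = lab_full == "vessel",
                             bleeding = lab_full == "bleeding",
                             specular = spec_mask),
                delta_hbo_true = hbo_true, delta_hbr_true = hbr_true,
                class_signals = signals)
  structure(list(cube = out_cube, truth = truth, dpf = dpf, spec = spec,
                 models = list(blood = blood, cortex = cortex)),
            class = "phantom")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %dx%d px, %d frames @ %g fps; resp %.3g Hz, cardiac %.3g Hz; noise_sigma %g; seed %d\n",
    x$height, x$width, x$n_frames, x$fps, x$respiration_hz, x$cardiac_hz,
    x$noise_sigma, x$seed))
  invisible(x)
}

#' @export
print.phantom <- function(x, ...) {
  print(x$spec)
  cat("class pixel counts:\n")
  print(table(x$truth$labels))
  invisible(x)
}
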