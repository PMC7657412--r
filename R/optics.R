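#' Tissue optical model
#'
#' Parameterizes the absorption and reduced-scattering spectra of a tissue.
#' Absorption follows a blood-fraction mixing model,
#' `mua(lambda) = B*S*mua_HbO(lambda) + B*(1-S)*mua_HbR(lambda) + mua0`,
#' where `B` is the blood volume fraction, `S` the oxygen saturation, and
#' `mua0` a baseline absorption. Reduced scattering follows the power law
#' `mus'(lambda) = scat_prefactor * (lambda/500)^(-scat_power)` (mm^-1, lambda
#' in nm), so `scat_prefactor` is mus' at 500 nm.
#'
#' @param B blood volume fraction (unitless, >= 0).
#' @param S oxygen saturation in `[0, 1]`.
#' @param mua0 baseline absorption coefficient (mm^-1, >= 0).
#' @param scat_prefactor mus' at 500 nm (mm^-1, > 0).
#' @param scat_power scattering power-law exponent.
#' @param name tissue label.
#' @return object of class `tissue_model`.
#' @export
#' @examples
#' blood <- tissue_preset("blood_patient1")
#' reduced_scattering(blood, 500)   # 2.2 mm^-1
tissue_model <- function(B, S, mua0, scat_prefactor, scat_power,
                         name = "tissue") {
  if (!is.finite(S) || S < 0 || S > 1) stop("S must be in [0, 1]")
  if (!is.finite(B) || B < 0) stop("B must be >= 0")
  if (!is.finite(mua0) || mua0 < 0) stop("mua0 must be >= 0")
  if (!is.finite(scat_prefactor) || scat_prefactor <= 0)
    stop("scat_prefactor must be > 0")
  structure(list(B = B, S = S, mua0 = mua0,
                 scat_prefactor = scat_prefactor, scat_power = scat_power,
                 name = name),
            class = "tissue_model")
}

#' Named tissue-model presets
#'
#' Presets mirror the per-patient blood/cortex parameter sets used by the
#' method (blood: B = 1, S = 0.98-0.99; cortex: B = 0.5, S = 0.9; baseline
#' absorption 0.001 or 0.01 mm^-1) together with the fixed scattering power
#' laws (blood 2.2*(lambda/500)^-0.66, cortex 2.42*(lambda/500)^-1.661).
#' They are read from `extdata/tissue_presets.json`.
#'
#' @param name preset name, e.g. `"blood_patient1"`, `"cortex_default"`.
#' @return a [tissue_model()].
#' @export
tissue_preset <- function(name) {
  path <- system.file("extdata", "tissue_presets.json", package = "hemoseg")
  presets <- jsonlite::read_json(path)
  presets[["_comment"]] <- NULL
  if (!name %in% names(presets))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(presets), collapse = ", ")))
  p <- presets[[name]]
  if (!is.null(p$alias)) p <- presets[[p$alias]]
  tissue_model(p$B, p$S, p$mua0, p$scat_prefactor, p$scat_power, name = name)
}

#' Absorption coefficient spectrum of a tissue model
#'
#' @param model a [tissue_model()].
#' @param ext an [extinction_table()].
#' @param wavelengths query wavelengths (nm) inside the extinction grid.
#' @return mua(lambda) in mm^-1, one value per wavelength.
#' @export
absorption_spectrum <- function(model, ext, wavelengths) {
  stopifnot(inherits(model, "tissue_model"))
  e <- extinction_at(ext, wavelengths)
  model$B * model$S * e$mua_hbo +
    model$B * (1 - model$S) * e$mua_hbr + model$mua0
}

#' Reduced scattering coefficient spectrum
#'
#' @inheritParams absorption_spectrum
#' @param wavelengths wavelengths in nm, > 0 (not restricted to the
#'   extinction grid).
#' @return mus'(lambda) in mm^-1.
#' @export
reduced_scattering <- function(model, wavelengths) {
  stopifnot(inherits(model, "tissue_model"))
  wavelengths <- as.numeric(wavelengths)
  if (any(!is.finite(wavelengths)) || any(wavelengths <= 0))
    stop("wavelengths must be positive")
  model$scat_prefactor * (wavelengths / 500)^(-model$scat_power)
}

# Groenhuis/Egan empirical internal-reflection parameter for relative
# refractive index n (tissue/air mismatch).
internal_reflection_A <- function(n = 1.4) {
  rd <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 + rd) / (1 - rd)
}

#' Total diffuse reflectance of a semi-infinite medium
#'
#' Closed-form diffusion-approximation estimate of the total (spatially
#' integrated) diffuse reflectance of a homogeneous semi-infinite medium,
#' parameterized by the transport albedo `a' = mus'/(mua + mus')` and the
#' internal-reflection parameter `A(n)`:
#' `Rd = (a'/2) * (1 + exp(-(4/3) A sqrt(3(1-a')))) * exp(-sqrt(3(1-a')))`.
#' The form is exact in the lossless limit (`Rd -> 1` as `mua -> 0`), lies in
#' `[0, 1]`, and is strictly decreasing in `mua` at fixed `mus'`. Identified
#' by `formula_id = "diffusion_semiinf_albedo_A"`.
#'
#' @param mua absorption coefficient(s), mm^-1, >= 0.
#' @param musp reduced scattering coefficient(s), mm^-1, > 0.
#' @param n relative refractive index for the internal-reflection parameter
#'   (default 1.4, tissue against air).
#' @return reflectance values in `[0, 1]`, recycled over the longer input.
#' @export
diffuse_reflectance <- function(mua, musp, n = 1.4) {
  if (any(!is.finite(mua)) || any(mua < 0)) stop("mua must be >= 0")
  if (any(!is.finite(musp)) || any(musp <= 0)) stop("musp must be > 0")
  A <- internal_reflection_A(n)
  ap <- musp / (mua + musp)
  s <- sqrt(3 * (1 - ap))
  (ap / 2) * (1 + exp(-(4 / 3) * A * s)) * exp(-s)
}

attr(diffuse_reflectance, "formula_id") <- "diffusion_semiinf_albedo_A"

#' Model diffuse reflectance spectrum at band centers
#'
#' Composes [absorption_spectrum()], [reduced_scattering()] and
#' [diffuse_reflectance()] per band. Each band is treated as a delta function
#' at its center wavelength; an optional rectangular bandpass of `bandwidth`
#' nm (trapezoid-integrated at 1 nm steps) can be enabled.
#'
#' @inheritParams absorption_spectrum
#' @param bands band-center wavelengths (nm).
#' @param n relative refractive index passed to [diffuse_reflectance()].
#' @param bandwidth full width (nm) of a rectangular band response; 0
#'   (default) evaluates at band centers only.
#' @return object of class `reflectance_spectrum`: list with
#'   `wavelengths_nm` and `reflectance` in `[0, 1]`.
#' @export
model_reflectance_spectrum <- function(model, ext, bands, n = 1.4,
                                       bandwidth = 0) {
  bands <- as.numeric(bands)
  one <- function(wl) {
    diffuse_reflectance(absorption_spectrum(model, ext, wl),
                        reduced_scattering(model, wl), n = n)
  }
  if (bandwidth > 0) {
    refl <- vapply(bands, function(b) {
      wl <- seq(b - bandwidth / 2, b + bandwidth / 2, by = 1)
      mean(one(wl))
    }, numeric(1))
  } else {
    refl <- one(bands)
  }
  structure(list(wavelengths_nm = bands, reflectance = refl,
                 tissue = model$name),
            class = "reflectance_spectrum")
}

#' Differential pathlength factor (CW semi-infinite diffusion)
#'
#' The multiplier converting a unit reference depth into mean photon
#' pathlength in the modified Beer-Lambert law, computed from the simple
#' continuous-wave semi-infinite diffusion closed form
#' `DPF = 0.5 * sqrt(3 * mus' / mua)` (`formula_id = "cw_semiinf_sqrt"`).
#' Monotone decreasing in `mua` at fixed `mus'` and invariant under joint
#' rescaling of both coefficients.
#'
#' @param mua absorption coefficient(s), mm^-1, > 0 (the lossless limit
#'   diverges and is rejected).
#' @param musp reduced scattering coefficient(s), mm^-1, > 0.
#' @return positive DPF value(s), unitless.
#' @export
differential_pathlength <- function(mua, musp) {
  if (any(!is.finite(mua)) || any(mua <= 0))
    stop("mua must be > 0 (DPF diverges as mua -> 0)")
  if (any(!is.finite(musp)) || any(musp <= 0)) stop("musp must be > 0")
  0.5 * sqrt(3 * musp / mua)
}

attr(differential_pathlength, "formula_id") <- "cw_semiinf_sqrt"

#' DPF sampled at band centers for a tissue model
#'
#' Evaluates [differential_pathlength()] at each band center using the
#' model's own absorption and scattering spectra, so the inversion shares the
#' forward module's optical assumptions.
#'
#' @inheritParams model_reflectance_spectrum
#' @return object of class `optical_path_model`: list with `wavelengths_nm`,
#'   `dpf`, `formula_id`.
#' @export
dpf_for_model <- function(model, ext, bands) {
  bands <- as.numeric(bands)
  dpf <- differential_pathlength(absorption_spectrum(model, ext, bands),
                                 reduced_scattering(model, bands))
  structure(list(wavelengths_nm = bands, dpf = dpf,
                 formula_id = "cw_semiinf_sqrt", tissue = model$name),
            class = "optical_path_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf(
    "<tissue_model '%s'> B=%g S=%g mua0=%g mm^-1; mus' = %g*(lambda/500)^-%g\n",
    x$name, x$B, x$S, x$mua0, x$scat_prefactor, x$scat_power))
  invisible(x)
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cat(sprintf("<reflectance_spectrum '%s'> %d bands %g-%g nm, R in [%.4g, %.4g]\n",
              x$tissue %||% "?", length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm),
              min(x$reflectance), max(x$reflectance)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
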