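#' Whole-blood hemoglobin absorption table
#'
#' Loads the wavelength-gridded absorption coefficients of fully oxygenated
#' (HbO) and fully deoxygenated (HbR) whole blood used by the forward optical
#' model and the modified Beer-Lambert inversion. The table shipped with the
#' package is a smooth synthetic reconstruction of the standard visible-band
#' hemoglobin spectra (peak positions and magnitudes of the oxyhemoglobin
#' 540/577 nm double peak, the deoxyhemoglobin 555 nm band, and the red-edge
#' fall-off), normalized to a whole-blood hemoglobin concentration of 150 g/L.
#'
#' @param path CSV file with columns `wavelength_nm`, `mua_hbo_mm1`,
#'   `mua_hbr_mm1`; defaults to the table shipped with the package. Comment
#'   lines starting with `#` are skipped; a
#'   `reference_hb_concentration_g_per_l:` comment documents the
#'   normalization.
#' @return An object of class `extinction_table`: list with
#'   `wavelengths_nm`, `mua_hbo`, `mua_hbr` (mm^-1) and
#'   `reference_hb_g_per_l`.
#' @export
#' @examples
#' ext <- hb_extinction()
#' range(ext$wavelengths_nm)
hb_extinction <- function(path = system.file("extdata",
                                             "hb_extinction_synthetic.csv",
                                             package = "hemoseg")) {
  stopifnot(file.exists(path))
  header <- readLines(path, n = 10L)
  conc <- 150
  m <- regmatches(header, regexpr("reference_hb_concentration_g_per_l:\\s*[0-9.]+", header))
  if (length(m)) conc <- as.numeric(sub(".*:\\s*", "", m[[1]]))
  tab <- utils::read.csv(path, comment.char = "#")
  extinction_table(tab$wavelength_nm, tab$mua_hbo_mm1, tab$mua_hbr_mm1, conc)
}

#' Construct an extinction table
#'
#' @param wavelengths_nm strictly increasing wavelength grid (nm).
#' @param mua_hbo,mua_hbr absorption coefficients of fully oxygenated /
#'   deoxygenated whole blood on that grid (mm^-1), all positive.
#' @param reference_hb_g_per_l hemoglobin concentration (g/L) the whole-blood
#'   normalization refers to.
#' @return `extinction_table` object.
#' @export
extinction_table <- function(wavelengths_nm, mua_hbo, mua_hbr,
                             reference_hb_g_per_l = 150) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  mua_hbo <- as.numeric(mua_hbo)
  mua_hbr <- as.numeric(mua_hbr)
  if (length(wavelengths_nm) < 2L || any(diff(wavelengths_nm) <= 0))
    stop("wavelength grid must be strictly increasing with >= 2 points")
  if (length(mua_hbo) != length(wavelengths_nm) ||
      length(mua_hbr) != length(wavelengths_nm))
    stop("mua_hbo and mua_hbr must share the wavelength grid")
  if (any(!is.finite(mua_hbo)) || any(!is.finite(mua_hbr)) ||
      any(mua_hbo <= 0) || any(mua_hbr <= 0))
    stop("absorption coefficients must be finite and positive")
  structure(list(wavelengths_nm = wavelengths_nm,
                 mua_hbo = mua_hbo, mua_hbr = mua_hbr,
                 reference_hb_g_per_l = reference_hb_g_per_l),
            class = "extinction_table")
}

#' Interpolate the extinction table onto query wavelengths
#'
#' Linear interpolation in wavelength; querying outside the tabulated range is
#' an error (the table is not extrapolated).
#'
#' @param ext an [extinction_table()].
#' @param wavelengths query wavelengths (nm), inside the grid.
#' @return list with vectors `mua_hbo`, `mua_hbr` (mm^-1) at `wavelengths`.
#' @export
extinction_at <- function(ext, wavelengths) {
  stopifnot(inherits(ext, "extinction_table"))
  wavelengths <- as.numeric(wavelengths)
  rng <- range(ext$wavelengths_nm)
  if (any(wavelengths < rng[1] | wavelengths > rng[2]))
    stop(sprintf("wavelength outside tabulated range [%g, %g] nm",
                 rng[1], rng[2]))
  list(
    mua_hbo = stats::approx(ext$wavelengths_nm, ext$mua_hbo, wavelengths)$y,
    mua_hbr = stats::approx(ext$wavelengths_nm, ext$mua_hbr, wavelengths)$y)
}

#' @export
print.extinction_table <- function(x, ...) {
  cat(sprintf(
    "<extinction_table> %d wavelengths %g-%g nm, whole blood at %g g/L Hb\n",
    length(x$wavelengths_nm), min(x$wavelengths_nm), max(x$wavelengths_nm),
    x$reference_hb_g_per_l))
  invisible(x)
}
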