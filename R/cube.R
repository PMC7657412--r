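#' Multispectral video cube
#'
#' Container for a multispectral reflectance video: a 4-D array indexed
#' `[frame, band, row, col]` plus acquisition metadata. Data are either raw
#' detector counts or calibrated reflectance (see [calibrate_cube()]).
#' Conventions used throughout the package: pixel indices are `(row, col)`,
#' frame and band indices start at 1 (R convention), band centers are strictly
#' increasing.
#'
#' @param data numeric array `T x B x H x W`.
#' @param fps frame rate in Hz (> 0).
#' @param band_centers_nm strictly increasing band-center wavelengths, length
#'   equal to `dim(data)[2]`.
#' @param calibrated logical flag; calibrated data must be finite and >= 0.
#' @param saturation_value detector maximum used for specular masking
#'   (`NULL` if unknown).
#' @return object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, fps, band_centers_nm, calibrated = FALSE,
                          saturation_value = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("data must be a 4-D array [frame, band, row, col]")
  if (!is.finite(fps) || fps <= 0) stop("fps must be > 0")
  band_centers_nm <- as.numeric(band_centers_nm)
  if (length(band_centers_nm) != dim(data)[2])
    stop("band_centers_nm length must match dim(data)[2]")
  if (any(diff(band_centers_nm) <= 0))
    stop("band centers must be strictly increasing")
  if (calibrated && (any(!is.finite(data)) || any(data < 0)))
    stop("calibrated data must be finite and >= 0")
  structure(list(data = data, fps = fps, band_centers_nm = band_centers_nm,
                 calibrated = calibrated, saturation_value = saturation_value),
            class = "spectral_cube")
}

#' Default 16-band grid, 480-630 nm
#'
#' Band centers of the 4x4 snapshot-mosaic camera layout emulated by the
#' phantom: 16 bands spanning 480 to 630 nm.
#' @return numeric vector of 16 wavelengths (nm).
#' @export
default_band_centers <- function() seq(480, 630, by = 10)

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<spectral_cube> %d frames x %d bands x %dx%d px @ %g fps (%s)\n",
    d[1], d[2], d[3], d[4], x$fps,
    if (x$calibrated) "calibrated reflectance" else "raw counts"))
  invisible(x)
}

#' Row-major default mosaic layout
#'
#' Maps mosaic cell `(i, j)` (1-based) of the 4x4 filter tile to band index
#' `4*(i-1) + j`. The vendor layout is configurable: any 4x4 matrix that is a
#' bijection onto 1..16 is accepted by [demosaic()].
#' @return 4x4 integer matrix of band indices.
#' @export
default_mosaic_layout <- function() matrix(1:16, nrow = 4, byrow = TRUE)

#' Demosaic a snapshot-mosaic frame
#'
#' Splits a raw frame from a 4x4 filter-array sensor into 16 band images by
#' subsampling each mosaic cell, reducing each spatial dimension by 4 (e.g. a
#' 1024x2048 frame becomes 16 bands of 256x512).
#'
#' @param frame numeric matrix `H x W`, `H` and `W` multiples of 4.
#' @param layout 4x4 matrix mapping mosaic cell (row, col) to band index;
#'   must be a bijection onto 1..16.
#' @return numeric array `16 x H/4 x W/4`.
#' @export
demosaic <- function(frame, layout = default_mosaic_layout()) {
  if (!is.matrix(frame)) stop("frame must be a matrix")
  d <- dim(frame)
  if (any(d %% 4 != 0)) stop("frame dimensions must be multiples of 4")
  if (!identical(sort(as.integer(layout)), 1:16))
    stop("layout must be a bijection between 16 mosaic cells and band indices")
  out <- array(NA_real_, c(16L, d[1] %/% 4L, d[2] %/% 4L))
  for (i in 1:4) for (j in 1:4) {
    out[layout[i, j], , ] <- frame[seq(i, d[1], by = 4), seq(j, d[2], by = 4)]
  }
  out
}

#' Reassemble a mosaic frame from band images
#'
#' Inverse of [demosaic()] under the same layout.
#' @param bands array `16 x h x w`.
#' @inheritParams demosaic
#' @return matrix `4h x 4w`.
#' @export
remosaic <- function(bands, layout = default_mosaic_layout()) {
  stopifnot(is.array(bands), length(dim(bands)) == 3L, dim(bands)[1] == 16L)
  h <- dim(bands)[2]; w <- dim(bands)[3]
  out <- matrix(NA_real_, 4 * h, 4 * w)
  for (i in 1:4) for (j in 1:4) {
    out[seq(i, 4 * h, by = 4), seq(j, 4 * w, by = 4)] <- bands[layout[i, j], , ]
  }
  out
}

#' Calibrate a cube against a reflectance standard
#'
#' Divides the raw cube, per pixel and band, by the time-reduced reflectance
#' standard (median over the standard's frames, robust to transient glints).
#' Pixels where the standard is zero cannot be calibrated; they are reported
#' in the `invalid_mask` attribute and set to `NA`, never silently divided.
#'
#' @param raw a raw [spectral_cube()].
#' @param standard a [spectral_cube()] measured on a reflectance standard with
#'   the same band count and spatial shape (any number of frames).
#' @return calibrated `spectral_cube`; attribute `invalid_mask` is an `H x W`
#'   logical matrix marking pixels unusable in any band.
#' @export
calibrate_cube <- function(raw, standard) {
  stopifnot(inherits(raw, "spectral_cube"), inherits(standard, "spectral_cube"))
  dr <- dim(raw$data); ds <- dim(standard$data)
  if (!identical(dr[-1], ds[-1]))
    stop("standard must match the raw cube in bands and spatial shape")
  ref <- apply(standard$data, c(2, 3, 4), stats::median)   # B x H x W
  bad <- ref == 0
  ref[bad] <- NA_real_
  out <- raw$data / rep(ref, each = dr[1])
  invalid <- apply(bad, c(2, 3), any)
  if (any(invalid))
    warning(sprintf("%d pixel(s) have a zero standard in some band; set to NA",
                    sum(invalid)))
  cube <- spectral_cube(out, raw$fps, raw$band_centers_nm, calibrated = FALSE,
                        saturation_value = raw$saturation_value)
  cube$calibrated <- TRUE   # may contain NA at invalid pixels
  attr(cube, "invalid_mask") <- invalid
  cube
}

#' Specular / saturation mask
#'
#' Marks every pixel that reaches the detector saturation value in any band
#' of any frame; such pixels are specular glints and are excluded from all
#' downstream maps and never assigned a tissue class other than `specular`.
#'
#' @param cube a [spectral_cube()] with `saturation_value` set.
#' @return `H x W` logical matrix (TRUE = specular), class `pixel_mask` with
#'   attribute `kind = "specular"`.
#' @export
specular_mask <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (is.null(cube$saturation_value))
    stop("cube has no saturation_value set")
  m <- apply(cube$data >= cube$saturation_value, c(3, 4), any)
  structure(m, class = c("pixel_mask", class(m)), kind = "specular")
}

# ---- cube / mask IO: multi-page float TIFF + JSON sidecar -------------------

#' Write a spectral cube to a TIFF stack with a JSON sidecar
#'
#' Pages are ordered frame-major (frame 1 bands 1..B, frame 2 bands 1..B, ...)
#' as 32-bit float TIFF; `<stem>.json` records fps, band centers, calibration
#' flag, saturation value and array dimensions.
#'
#' @param cube a [spectral_cube()].
#' @param stem output path without extension.
#' @return invisibly, the TIFF path.
#' @export
write_cube <- function(cube, stem) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$data)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) for (b in seq_len(d[2])) {
    pages[[k]] <- matrix(cube$data[t, b, , ], d[3], d[4])
    k <- k + 1L
  }
  tif <- paste0(stem, ".tiff")
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(fps = cube$fps, band_centers_nm = cube$band_centers_nm,
               calibrated = cube$calibrated,
               saturation_value = cube$saturation_value,
               dims = list(frames = d[1], bands = d[2],
                           height = d[3], width = d[4]),
               page_order = "frame_major")
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(tif)
}

#' Read a spectral cube written by [write_cube()]
#'
#' @param stem path without extension (expects `<stem>.tiff` and
#'   `<stem>.json`).
#' @return a [spectral_cube()].
#' @export
read_cube <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(stem, ".tiff"), all = TRUE)
  d <- meta$dims
  data <- array(NA_real_, c(d$frames, d$bands, d$height, d$width))
  k <- 1L
  for (t in seq_len(d$frames)) for (b in seq_len(d$bands)) {
    data[t, b, , ] <- pages[[k]]
    k <- k + 1L
  }
  spectral_cube(data, meta$fps, meta$band_centers_nm,
                calibrated = isTRUE(meta$calibrated),
                saturation_value = meta$saturation_value)
}

#' Write / read a binary pixel mask as PNG
#'
#' @param mask `H x W` logical matrix.
#' @param path PNG file path.
#' @return `write_mask` returns the path invisibly; `read_mask` returns a
#'   logical matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}
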