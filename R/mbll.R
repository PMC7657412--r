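#' Attenuation change relative to a baseline
#'
#' Per pixel and band, `dA(lambda, t) = -log10(R(lambda, t) / R0(lambda))`
#' where `R0` is the baseline reflectance of that pixel/band: the time mean
#' over the analyzed window (default) or the mean over an explicit frame
#' range. Pixels with nonpositive reflectance anywhere cannot be
#' log-transformed; they are added to the exclusion mask (attribute
#' `excluded`, with a reported count), not silently dropped.
#'
#' @param cube a calibrated [spectral_cube()].
#' @param baseline `"mean"` (default) or an integer vector of frame indices
#'   whose mean defines `R0`.
#' @return numeric array `T x B x H x W` of attenuation changes (base-10),
#'   with attributes `excluded` (`H x W` logical) and `baseline_spec`.
#' @export
delta_attenuation <- function(cube, baseline = "mean") {
  stopifnot(inherits(cube, "spectral_cube"))
  if (!cube$calibrated) stop("cube must be calibrated before MBLL inversion")
  x <- cube$data
  d <- dim(x)
  bad_px <- apply(x <= 0 | !is.finite(x), c(3, 4), any)
  if (any(bad_px))
    message(sprintf("delta_attenuation: excluding %d pixel(s) with nonpositive reflectance",
                    sum(bad_px)))
  if (identical(baseline, "mean")) {
    frames <- seq_len(d[1])
    spec <- "mean over full window"
  } else {
    frames <- as.integer(baseline)
    if (any(frames < 1L | frames > d[1])) stop("baseline frames out of range")
    spec <- sprintf("mean over frames %d-%d", min(frames), max(frames))
  }
  r0 <- apply(x[frames, , , , drop = FALSE], c(2, 3, 4), mean)  # B x H x W
  da <- -(log10(x) - rep(log10(r0), each = d[1]))
  da[!is.finite(da)] <- NA_real_
  attr(da, "excluded") <- bad_px
  attr(da, "baseline_spec") <- spec
  da
}

#' MBLL design matrix at band centers
#'
#' Columns are the effective base-10 absorptivities of HbO and HbR per uM of
#' concentration change, times the per-band differential pathlength factor
#' and a 1 mm reference depth:
#' `M[lambda, c] = mua_c(lambda) / (ln(10) * C_ref_uM) * DPF(lambda)`,
#' with `C_ref_uM` the whole-blood reference hemoglobin concentration of the
#' extinction table expressed in uM. Concentration changes recovered against
#' this design are in uM (convention-dependent; see the methods vignette).
#'
#' @param ext an [extinction_table()].
#' @param dpf an `optical_path_model` from [dpf_for_model()], sampled at the
#'   same band centers.
#' @param bands band-center wavelengths (nm).
#' @return `length(bands) x 2` matrix, columns `hbo`, `hbr`.
#' @export
mbll_design <- function(ext, dpf, bands) {
  bands <- as.numeric(bands)
  if (length(bands) < 2L) stop("need >= 2 bands for a 2-chromophore inversion")
  if (!isTRUE(all.equal(dpf$wavelengths_nm, bands)))
    stop("DPF must be sampled at the cube's band centers")
  e <- extinction_at(ext, bands)
  c_ref_um <- ext$reference_hb_g_per_l / 64500 * 1e6   # g/L -> uM (64.5 kDa)
  m <- cbind(hbo = e$mua_hbo, hbr = e$mua_hbr) / (log(10) * c_ref_um) * dpf$dpf
  if (qr(m)$rank < 2L) stop("rank-deficient MBLL design (degenerate band set)")
  m
}

#' Invert the modified Beer-Lambert law
#'
#' Per pixel and frame, solves the ordinary least-squares problem
#' `dA(lambda) = M %*% c(dHbO, dHbR)` over the bands, where `M` is
#' [mbll_design()]. Unconstrained by design: concentration changes are signed.
#'
#' @param da attenuation-change array `T x B x H x W` from
#'   [delta_attenuation()] (or `T x B` matrix for a single pixel).
#' @inheritParams mbll_design
#' @param fps frame rate (Hz), stored on the result.
#' @return object of class `chromophore_maps`: list with `delta_hbo`,
#'   `delta_hbr` (`T x H x W` arrays, uM), `fps`, `baseline_spec`, and the
#'   exclusion mask `excluded`.
#' @export
invert_mbll <- function(da, ext, dpf, bands, fps) {
  m <- mbll_design(ext, dpf, bands)
  single <- is.matrix(da)
  if (single) da <- array(da, c(dim(da), 1L, 1L))
  d <- dim(da)
  if (d[2] != nrow(m)) stop("band count mismatch between da and design")
  # pseudo-inverse applied to bands-major reshape
  pinv <- solve(crossprod(m), t(m))                     # 2 x B
  flat <- aperm(da, c(2, 1, 3, 4))
  dim(flat) <- c(d[2], d[1] * d[3] * d[4])
  flat[is.na(flat)] <- 0
  sol <- pinv %*% flat                                  # 2 x (T*H*W)
  shape <- c(d[1], d[3], d[4])
  hbo <- array(sol[1, ], shape)
  hbr <- array(sol[2, ], shape)
  excl <- attr(da, "excluded") %||% matrix(FALSE, d[3], d[4])
  if (any(excl)) {
    hbo[rep(excl, each = d[1])] <- NA_real_
    hbr[rep(excl, each = d[1])] <- NA_real_
  }
  structure(list(delta_hbo = hbo, delta_hbr = hbr, fps = fps,
                 baseline_spec = attr(da, "baseline_spec") %||% "unknown",
                 excluded = excl),
            class = "chromophore_maps")
}

#' Forward MBLL: attenuation changes from concentration changes
#'
#' Builds `dA(lambda, t) = M %*% c(dHbO(t), dHbR(t))` with the same design
#' matrix as the inversion; used by the phantom generator so that forward and
#' inverse models are self-consistent.
#'
#' @param delta_hbo,delta_hbr concentration-change series (uM), equal length.
#' @inheritParams mbll_design
#' @return `T x B` matrix of attenuation changes.
#' @export
forward_mbll <- function(delta_hbo, delta_hbr, ext, dpf, bands) {
  stopifnot(length(delta_hbo) == length(delta_hbr))
  m <- mbll_design(ext, dpf, bands)
  cbind(delta_hbo, delta_hbr) %*% t(m)
}

#' @export
print.chromophore_maps <- function(x, ...) {
  d <- dim(x$delta_hbo)
  cat(sprintf("<chromophore_maps> %d frames x %dx%d px @ %g fps; baseline: %s\n",
              d[1], d[2], d[3], x$fps, x$baseline_spec))
  invisible(x)
}
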