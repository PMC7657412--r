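#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end run in one validated list.
#' Defaults are the method's published operating point: activity band
#' 0.03-0.3 Hz, spectral thresholds `a_blood > 0.8` and `a_cortex > 0.75`,
#' dynamic threshold at the 75th percentile of the bleeding seed region.
#'
#' @param f_lo,f_hi hemodynamic activity band (Hz).
#' @param t_blood,t_cortex spectral proportion thresholds in `(0, 1)`.
#' @param dynamic `"auto"` (percentile of the bleeding seed) or a numeric
#'   manual threshold override.
#' @param percentile percentile (0-100) used when `dynamic = "auto"`.
#' @param normalization proportion normalization, `"clip"` or `"sum"`.
#' @param blood_model,cortex_model tissue presets (names or
#'   [tissue_model()]s) used for the model reflectance spectra and DPF.
#' @param baseline MBLL baseline spec (see [delta_attenuation()]).
#' @param seed RNG seed recorded with the run.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(f_lo = 0.03, f_hi = 0.3,
                            t_blood = 0.8, t_cortex = 0.75,
                            dynamic = "auto", percentile = 75,
                            normalization = c("clip", "sum"),
                            blood_model = "blood_patient1",
                            cortex_model = "cortex_patient1",
                            baseline = "mean", seed = 0) {
  normalization <- match.arg(normalization)
  stopifnot(f_lo > 0, f_hi > f_lo,
            t_blood > 0, t_blood < 1, t_cortex > 0, t_cortex < 1,
            percentile >= 0, percentile <= 100)
  if (!identical(dynamic, "auto") && !is.numeric(dynamic))
    stop("dynamic must be \"auto\" or a numeric threshold")
  structure(list(f_lo = f_lo, f_hi = f_hi, t_blood = t_blood,
                 t_cortex = t_cortex, dynamic = dynamic,
                 percentile = percentile, normalization = normalization,
                 blood_model = blood_model, cortex_model = cortex_model,
                 baseline = baseline, seed = seed),
            class = "pipeline_config")
}

#' Run the full segmentation pipeline
#'
#' Chains the stages of the three-step method on a calibrated cube:
#' specular masking; modified Beer-Lambert inversion into dHbO/dHbR;
#' per-pixel amplitude spectra of dHbO with SNV normalization; the
#' band-averaged activity metric; spectral blood/cortex unmixing of the
#' time-mean reflectance; the dynamic/static threshold from the bleeding
#' seed region; and label fusion. A bleeding seed region (manual in the
#' clinical workflow) must be supplied unless `input` is a phantom, whose
#' ground-truth bleeding mask is used by default.
#'
#' @param input a `phantom` from [generate_phantom()], or a calibrated
#'   [spectral_cube()].
#' @param config a [pipeline_config()].
#' @param bleeding_seed `H x W` logical mask of a known pooled-blood region
#'   (required for plain cubes; defaults to the phantom's ground truth).
#' @param ext an [extinction_table()].
#' @return object of class `hemoseg_run`: list with `segmentation`
#'   ([fuse_labels()] result), `metric`, `spectrum` (SNV), `proportions`,
#'   `chromophores`, `specular`, `config`, and `summary` (label counts,
#'   thresholds used, respiratory/cardiac peak frequencies of the image-mean
#'   SNV spectrum).
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         bleeding_seed = NULL, ext = hb_extinction()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(input, "phantom")) {
    cube <- input$cube
    if (is.null(bleeding_seed)) bleeding_seed <- input$truth$masks$bleeding
  } else if (inherits(input, "spectral_cube")) {
    cube <- input
  } else stop("input must be a phantom or a spectral_cube")
  if (!cube$calibrated) stop("cube must be calibrated first (calibrate_cube)")
  if (is.null(bleeding_seed))
    stop("a bleeding seed region is required for non-phantom input")
  bands <- cube$band_centers_nm

  spec_mask <- if (!is.null(cube$saturation_value)) specular_mask(cube)
               else matrix(FALSE, dim(cube$data)[3], dim(cube$data)[4])

  as_model <- function(m) if (inherits(m, "tissue_model")) m else tissue_preset(m)
  blood_m <- as_model(config$blood_model)
  cortex_m <- as_model(config$cortex_model)
  dpf <- dpf_for_model(cortex_m, ext, bands)

  da <- delta_attenuation(cube, baseline = config$baseline)
  chrom <- invert_mbll(da, ext, dpf, bands, fps = cube$fps)
  rm(da)
  spec <- snv_normalize(amplitude_spectrum(chrom$delta_hbo, cube$fps))
  metric <- band_metric(spec, config$f_lo, config$f_hi)

  mean_refl <- apply(cube$data, c(2, 3, 4), mean)
  r_blood <- model_reflectance_spectrum(blood_m, ext, bands)
  r_cortex <- model_reflectance_spectrum(cortex_m, ext, bands)
  props <- fit_spectral_proportions(mean_refl, r_blood, r_cortex,
                                    normalization = config$normalization)
  spectral <- classify_spectral(props, config$t_blood, config$t_cortex)

  thr <- if (identical(config$dynamic, "auto")) {
    dynamic_threshold(metric, bleeding_seed, config$percentile,
                      exclude = spec_mask)
  } else config$dynamic
  dynamic <- classify_dynamic(metric, thr, exclude = spec_mask)
  seg <- fuse_labels(spectral, dynamic, specular = spec_mask,
                     threshold_used = thr)

  resp_peak <- peak_frequency(spec, config$f_lo, config$f_hi)
  card_peak <- if (cube$fps / 2 > 1.0) {
    peak_frequency(spec, 1.0, min(1.7, cube$fps / 2))
  } else NA_real_
  summary <- list(label_counts = as.list(label_counts(seg)),
                  dynamic_threshold = thr,
                  t_blood = config$t_blood, t_cortex = config$t_cortex,
                  band_hz = c(config$f_lo, config$f_hi),
                  respiratory_peak_hz = resp_peak,
                  cardiac_peak_hz = card_peak,
                  n_frames = dim(cube$data)[1], fps = cube$fps,
                  seed = config$seed)
  structure(list(segmentation = seg, metric = metric, spectrum = spec,
                 proportions = props, chromophores = chrom,
                 specular = spec_mask, config = config, summary = summary),
            class = "hemoseg_run")
}

#' @export
print.hemoseg_run <- function(x, ...) {
  cat("<hemoseg_run>\n")
  print(x$segmentation)
  cat(sprintf("respiratory peak: %.4g Hz; cardiac peak: %.4g Hz\n",
              x$summary$respiratory_peak_hz, x$summary$cardiac_peak_hz))
  invisible(x)
}

#' Machine-readable run summary
#'
#' @param run a `hemoseg_run`.
#' @param path optional JSON output path.
#' @return the summary list, invisibly if written to `path`.
#' @export
run_summary <- function(run, path = NULL) {
  stopifnot(inherits(run, "hemoseg_run"))
  s <- run$summary
  if (!is.null(path)) {
    jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA)
    return(invisible(s))
  }
  s
}
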