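# hemoseg

Discriminating **bleeding, blood vessels, and cortex** in multispectral
diffuse-reflectance video of the exposed brain.

Pooled blood is one of the most stubborn confounders in intraoperative
optical imaging: spectrally it is almost indistinguishable from a blood
vessel, because hemoglobin dominates visible-band absorption in both. What
separates them is time — perfused structures carry hemodynamic fluctuations
(low-frequency oscillations, the ventilator-set respiratory rhythm, the
cardiac pulse) that pooled, static blood lacks. `hemoseg` implements a
three-stage classifier for calibrated multispectral video cubes
(T frames × 16 bands, 480–630 nm) that combines both cues, plus a synthetic
phantom generator so the entire pipeline is testable without patient data.

**The method.** Per pixel:

1. *Spectral unmixing.* The time-mean reflectance spectrum
   $R_d(\lambda)$ is fit by nonnegative least squares as
   $a_{\mathrm{blood}} R_{\mathrm{blood}}(\lambda) +
   a_{\mathrm{cortex}} R_{\mathrm{cortex}}(\lambda)$, where the end-member
   spectra come from a diffusion-approximation forward model with
   $\mu_a = B S \mu_{a,\mathrm{HbO}} + B(1-S)\mu_{a,\mathrm{HbR}} +
   \mu_{a,0}$ and power-law scattering
   ($\mu_s' = 2.2\,(\lambda/500)^{-0.66}$ mm⁻¹ for blood,
   $2.42\,(\lambda/500)^{-1.661}$ for cortex). Pixels with
   $a_{\mathrm{blood}} > 0.8$ are blood; $a_{\mathrm{cortex}} > 0.75$ are
   cortex.
2. *Hemodynamic activity.* A modified Beer–Lambert inversion converts
   reflectance time courses into ΔHbO(t); the mean SNV-normalized Fourier
   amplitude over **0.03–0.3 Hz** is thresholded at the 75th percentile of
   a pooled-blood seed region, splitting pixels into dynamic and static.
3. *Fusion.* blood ∧ dynamic → **vessel**; blood ∧ static → **bleeding**;
   cortex ∧ dynamic → **cortex**; saturated pixels are **specular**;
   everything else is unclassified.

See `vignettes/hemoseg-methods.Rmd` for the model details, the closed
forms chosen for the diffusion reflectance and the differential pathlength
factor, and the phantom design.

## Worked example

Generate the default phantom (64 × 64 px, 1200 frames at 20 fps — one
minute of "surgery" with respiration at 14 cycles/min and a heartbeat of
79 bpm) and run the full pipeline:

```r
library(hemoseg)

ph  <- generate_phantom(phantom_spec())
run <- run_pipeline(ph)
print(run)
#> <hemoseg_run>
#> <segmentation_result>
#>
#>       cortex       vessel     bleeding     specular unclassified
#>         3470          242          342           42            0
#> dynamic threshold used: -0.03722598
#> respiratory peak: 0.2333 Hz; cardiac peak: 1.317 Hz
```

Every ground-truth pixel is recovered: 3470 cortex, 242 vessel, and 342
bleeding pixels are labeled correctly, the 42 saturated pixels are flagged
specular, and the image-mean spectrum peaks at the set respiratory
(14/60 ≈ 0.233 Hz) and cardiac (79/60 ≈ 1.317 Hz) rates. The dynamic
threshold (−0.037) is the 75th percentile of the band metric inside the
bleeding seed region.

The separation the classifier exploits is visible in the region statistics
of the 0.03–0.3 Hz activity metric:

```r
region_compare(run$metric,
               ph$truth$masks[c("bleeding", "vessel", "cortex")],
               exclude = run$specular)
#> Kruskal-Wallis chi-squared = 4053, df = 2, p-value = 0
#> # A tibble: 3 × 8
#>   region       n     min     q25  median     q75     max    mean
#> 1 bleeding   342 -0.0372 -0.0372 -0.0372 -0.0372 -0.0372 -0.0372
#> 2 vessel     242  2.68    2.68    2.68    2.68    2.68    2.68
#> 3 cortex    3470  3.67    3.67    3.67    3.67    3.67    3.67
```

Pooled blood sits at an SNV activity of ≈ 0 (its spectrum is flat
instrument noise), vessels at 2.7, cortex at 3.7 — the ordering the
dynamic/static threshold relies on. `plot_labels(run)`,
`plot_metric(run$metric)` and `plot_region_spectra()` display the label
map, the activity map, and the region-mean spectra.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/hemoseg.R phantom --out out/ --seed 0
Rscript inst/cli/hemoseg.R run --cube out/cube --bleeding-seed out/bleeding.png --out run/
Rscript inst/cli/hemoseg.R sweep --phantom-seed 0 --out sweep/
```

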