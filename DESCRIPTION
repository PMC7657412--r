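Package: hemoseg
Title: Discriminating Bleeding, Blood Vessels, and Cortex in Multispectral
    Brain Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments intraoperative multispectral diffuse-reflectance video of
    the exposed brain into bleeding, blood vessels, and cortex. Combines a
    hemoglobin-based spectral unmixing of calibrated reflectance spectra
    (modified Beer-Lambert inversion, diffusion-approximation forward models of
    blood and cortex) with a temporal-frequency criterion on oxyhemoglobin
    concentration changes: perfused tissue carries low-frequency hemodynamic
    and respiratory components (0.03-0.3 Hz) that pooled blood lacks. Includes
    a synthetic phantom generator with ground-truth labels so the full pipeline
    is testable without patient data, and a minimal-acquisition-time window
    sweep analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    tibble,
    ggplot2,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
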